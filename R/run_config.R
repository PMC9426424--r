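#' Pipeline run configuration
#'
#' Bundles every tunable threshold of the pipeline. Defaults reproduce the
#' stringency of a conservative metagenomic SNV workflow: 20x minimum
#' coverage, 10% minimum departure from consensus, time points of interest at
#' >= 5 RPKM, abundance spikes at >= 30 RPKM, 10-bp linkage-decay bins,
#' five-gene F_ST windows, a >= 1x copy-number change rule and a 2.5-kb
#' minimum contig length.
#'
#' @param min_coverage minimum read coverage for a site to enter SNV calling.
#' @param min_departure minimum departure from consensus (1 - major allele
#'   frequency) for an SNV call.
#' @param min_rpkm_toi minimum RPKM for a sample to count as a time point of
#'   interest.
#' @param rpkm_spike RPKM threshold defining a single-sample abundance spike.
#' @param min_toi_count minimum number of qualifying samples for the
#'   persistent-population criterion.
#' @param ld_bin width (bp) of linkage-decay distance bins.
#' @param fst_window number of consecutive genes per F_ST window.
#' @param fst_sd_levels standard-deviation multipliers at which elevated F_ST
#'   windows are called.
#' @param genefreq_delta minimum max-minus-min gene frequency change (copies
#'   per genome) for a gene to be called variable.
#' @param min_contig_len minimum contig length (bp) for gene-frequency
#'   analysis.
#' @param dn_min retained dN/dS pairs must have dN strictly greater than this.
#' @param ds_range retained pairs must have dS strictly inside this interval.
#' @param dnds_max retained pairs must have dN/dS strictly below this.
#' @param alpha significance level for the sweep scan.
#' @param presence_threshold minimum read-pair count for a two-locus
#'   haplotype to count as present in the four-gamete test.
#' @param min_gene_sites minimum covered sites per gene per time point for
#'   the Welch sweep test.
#' @param seed optional integer random seed recorded with the run.
#'
#' @return an object of class `aquiferpop_config` (a named list).
#' @export
#' @examples
#' cfg <- run_config()
#' cfg$min_coverage
run_config <- function(min_coverage = 20L,
                       min_departure = 0.10,
                       min_rpkm_toi = 5,
                       rpkm_spike = 30,
                       min_toi_count = 3L,
                       ld_bin = 10L,
                       fst_window = 5L,
                       fst_sd_levels = c(1, 2),
                       genefreq_delta = 1.0,
                       min_contig_len = 2500L,
                       dn_min = 0,
                       ds_range = c(0.01, 1),
                       dnds_max = 5,
                       alpha = 0.05,
                       presence_threshold = 1L,
                       min_gene_sites = 10L,
                       seed = NULL) {
  cfg <- list(
    min_coverage = as.integer(min_coverage),
    min_departure = min_departure,
    min_rpkm_toi = min_rpkm_toi,
    rpkm_spike = rpkm_spike,
    min_toi_count = as.integer(min_toi_count),
    ld_bin = as.integer(ld_bin),
    fst_window = as.integer(fst_window),
    fst_sd_levels = fst_sd_levels,
    genefreq_delta = genefreq_delta,
    min_contig_len = as.integer(min_contig_len),
    dn_min = dn_min,
    ds_range = ds_range,
    dnds_max = dnds_max,
    alpha = alpha,
    presence_threshold = as.integer(presence_threshold),
    min_gene_sites = as.integer(min_gene_sites),
    seed = seed
  )
  num <- unlist(cfg[setdiff(names(cfg), "seed")])
  if (any(!is.finite(num)))
    stop("run_config: all thresholds must be finite")
  if (cfg$min_coverage <= 0 || cfg$min_departure <= 0 || cfg$ld_bin <= 0 ||
      cfg$fst_window <= 0 || cfg$min_contig_len <= 0 || cfg$alpha <= 0)
    stop("run_config: thresholds must be positive")
  structure(cfg, class = "aquiferpop_config")
}

#' @export
print.aquiferpop_config <- function(x, ...) {
  cat("aquiferpop run configuration\n")
  for (nm in setdiff(names(x), "seed"))
    cat(sprintf("  %-18s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  if (!is.null(x$seed)) cat(sprintf("  %-18s %s\n", "seed", x$seed))
  invisible(x)
}

#' Read / write a run configuration as a key = value text file
#'
#' Vector-valued fields are comma-separated. Unknown keys are rejected so a
#' typo cannot silently fall back to a default.
#'
#' @param path file path.
#' @return `read_run_config()` returns an `aquiferpop_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad))
    stop("config format error at line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- lapply(kv, function(p) as.numeric(strsplit(trimws(p[[2]]), ",")[[1]]))
  allowed <- names(formals(run_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, setNames(vals, keys))
}

#' @rdname read_run_config
#' @param cfg an `aquiferpop_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "aquiferpop_config"))
  keep <- setdiff(names(cfg), "seed")
  if (!is.null(cfg$seed)) keep <- c(keep, "seed")
  lines <- vapply(keep, function(nm)
    sprintf("%s = %s", nm, paste(cfg[[nm]], collapse = ",")), "")
  writeLines(lines, path)
  invisible(path)
}

#' Convert internal 0-based positions to 1-based report coordinates
#'
#' Internally every position is a 0-based offset; anything printed for a
#' human is 1-based. These helpers are the single conversion point.
#'
#' @param pos integer vector of positions.
#' @return integer vector.
#' @export
to_report_position <- function(pos) as.integer(pos) + 1L

#' @rdname to_report_position
#' @export
from_report_position <- function(pos) as.integer(pos) - 1L
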