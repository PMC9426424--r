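# Gene-specific sweep scan, Hudson F_ST windows, and gene-frequency CNV.

# Welch's two-sample t test, closed form, one-sided ("less": mean(x) <
# mean(y)). Deterministic on degenerate (zero-variance) inputs where
# stats::t.test errors: equal means -> p = 1, otherwise p = 0/1 by sign.
welch_p <- function(x, y, alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    if (m1 == m2) return(1)
    less <- m1 < m2
    if (alternative == "less") return(as.numeric(!less)) else return(0)
  }
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  if (alternative == "less") pt(t, df) else 2 * pt(-abs(t), df)
}

#' Gene-specific sweep scan via Welch's t test on per-site diversity
#'
#' For each gene and each time point of interest, tests one-sided whether
#' the gene's per-site pi values are lower than the genome-wide per-site pi
#' values (Welch's unequal-variance t). P-values are Benjamini-Hochberg
#' adjusted across genes within each time point (set `p_adjust = "none"`
#' for raw p). A gene is flagged iff significant in every time point.
#' Consecutive flagged genes (in the supplied gene order) are grouped into
#' runs.
#'
#' @param gene_pi named list (per time point) of named lists (per gene) of
#'   per-site pi vectors, zeros included for invariant covered sites (see
#'   [expand_pi_sites()]).
#' @param genome_pi named list (per time point) of genome-wide per-site pi
#'   vectors.
#' @param gene_order character vector of gene ids in genomic order.
#' @param cfg an [run_config()] object (`alpha`, `min_gene_sites`).
#' @param p_adjust `"BH"` (default) or `"none"`.
#' @param alternative `"less"` (default; sweep = lower diversity) or
#'   `"two.sided"`.
#' @return data.frame, one row per gene: `gene_id`, `p_<tp>` columns,
#'   `tested`, `flagged`, `run_id`, `run_length`.
#' @export
low_diversity_genes <- function(gene_pi, genome_pi, gene_order,
                                cfg = run_config(),
                                p_adjust = c("BH", "none"),
                                alternative = c("less", "two.sided")) {
  p_adjust <- match.arg(p_adjust)
  alternative <- match.arg(alternative)
  tps <- names(gene_pi)
  stopifnot(length(tps) >= 1, setequal(tps, names(genome_pi)))
  pm <- matrix(NA_real_, length(gene_order), length(tps),
               dimnames = list(gene_order, tps))
  tested <- setNames(rep(TRUE, length(gene_order)), gene_order)
  for (tp in tps) {
    for (g in gene_order) {
      x <- gene_pi[[tp]][[g]]
      if (is.null(x) || length(x) < cfg$min_gene_sites) {
        tested[g] <- FALSE
        next
      }
      pm[g, tp] <- welch_p(x, genome_pi[[tp]], alternative)
    }
    if (p_adjust == "BH") {
      ok <- !is.na(pm[, tp])
      pm[ok, tp] <- stats::p.adjust(pm[ok, tp], method = "BH")
    }
  }
  flagged <- tested & apply(pm < cfg$alpha, 1, function(r) all(!is.na(r) & r))
  runs <- rle(unname(flagged))
  run_id <- rep(NA_integer_, length(flagged))
  run_length <- rep(NA_integer_, length(flagged))
  idx <- cumsum(runs$lengths)
  rid <- 0L
  for (j in seq_along(runs$lengths)) {
    if (runs$values[j]) {
      rid <- rid + 1L
      sel <- (idx[j] - runs$lengths[j] + 1L):idx[j]
      run_id[sel] <- rid
      run_length[sel] <- runs$lengths[j]
    }
  }
  out <- data.frame(gene_id = gene_order, tested = unname(tested),
                    flagged = unname(flagged),
                    run_id = run_id, run_length = run_length)
  colnames(pm) <- paste0("p_", tps)
  cbind(out, as.data.frame(pm, row.names = NULL))
}

#' Hudson F_ST components for one site between two populations
#'
#' Returns the per-site numerator and denominator of the Hudson estimator;
#' multi-site F_ST must be aggregated as the ratio of sums, never the mean
#' of ratios. `numerator = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`,
#' `denominator = p1(1-p2) + p2(1-p1)`. Sites with zero denominator (both
#' populations fixed for the same allele) should be skipped by the caller.
#'
#' @param p1,p2 frequencies of the same tracked allele in the two
#'   populations (here: two time points).
#' @param n1,n2 sample sizes (read coverage at the site).
#' @return list with numeric vectors `numerator` and `denominator`.
#' @export
#' @examples
#' x <- hudson_fst_site(1, 100, 0, 100); x$numerator / x$denominator  # 1
hudson_fst_site <- function(p1, n1, p2, n2) {
  stopifnot(all(n1 >= 2), all(n2 >= 2))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(numerator = num, denominator = den)
}

#' Per-gene Hudson F_ST between two time points
#'
#' Aggregates per-site Hudson components within each gene as a ratio of
#' sums over the shared linked biallelic sites. Sites with zero denominator
#' are skipped; genes with no usable site are dropped.
#'
#' @param freqs data.frame with columns `contig, position, p1, n1, p2, n2`:
#'   tracked-allele frequencies and coverages at shared biallelic sites.
#' @param genes gene-model data.frame.
#' @return data.frame `gene_id, fst, n_sites`.
#' @export
fst_by_gene <- function(freqs, genes) {
  comp <- hudson_fst_site(freqs$p1, freqs$n1, freqs$p2, freqs$n2)
  usable <- comp$denominator > 0
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    in_gene <- usable & freqs$contig == g$contig &
      freqs$position >= g$start & freqs$position < g$end
    if (!any(in_gene)) return(NULL)
    data.frame(gene_id = g$gene_id,
               fst = sum(comp$numerator[in_gene]) /
                 sum(comp$denominator[in_gene]),
               n_sites = sum(in_gene))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), fst = numeric(),
                      n_sites = integer())
  out
}

#' Sliding five-gene window scan for elevated F_ST
#'
#' Slides a window of `cfg$fst_window` consecutive eligible genes (step 1)
#' along each contig, compares the window mean F_ST with the genome mean
#' plus k standard deviations of the per-gene F_ST distribution
#' (k in `cfg$fst_sd_levels`), and merges overlapping elevated windows into
#' regions. Eligibility filtering (complete start/stop codon, coverage
#' within 2 SD of the genome mean) is the caller's responsibility; see
#' [eligible_fst_genes()].
#'
#' @param gene_fst data.frame `gene_id, fst` for eligible genes.
#' @param genes gene-model data.frame giving contig and genomic order.
#' @param cfg an [run_config()] object.
#' @return list: `windows` (data.frame `contig, first_gene, last_gene,
#'   mean_fst` plus one logical `elevated_<k>sd` column per level) and
#'   `regions` (named integer vector of merged region counts per level).
#' @export
window_fst_scan <- function(gene_fst, genes, cfg = run_config()) {
  w <- cfg$fst_window
  genome_mean <- mean(gene_fst$fst)
  genome_sd <- sd(gene_fst$fst)
  ord <- genes[match(gene_fst$gene_id, genes$gene_id), c("contig", "start")]
  gf <- gene_fst[order(ord$contig, ord$start), , drop = FALSE]
  gf$contig <- ord$contig[order(ord$contig, ord$start)]
  win_rows <- list()
  for (ctg in unique(gf$contig)) {
    sub <- gf[gf$contig == ctg, , drop = FALSE]
    if (nrow(sub) < w) next
    for (i in seq_len(nrow(sub) - w + 1L)) {
      sel <- i:(i + w - 1L)
      win_rows[[length(win_rows) + 1L]] <- data.frame(
        contig = ctg, first = i, first_gene = sub$gene_id[sel[1]],
        last_gene = sub$gene_id[sel[w]], mean_fst = mean(sub$fst[sel]))
    }
  }
  levels <- cfg$fst_sd_levels
  if (!length(win_rows)) {
    return(list(windows = NULL,
                regions = setNames(integer(length(levels)),
                                   paste0("sd", levels))))
  }
  wins <- do.call(rbind, win_rows)
  regions <- integer(length(levels))
  names(regions) <- paste0("sd", levels)
  for (j in seq_along(levels)) {
    k <- levels[j]
    elev <- wins$mean_fst > genome_mean + k * genome_sd
    wins[[paste0("elevated_", k, "sd")]] <- elev
    # merge overlapping/adjacent elevated windows (per contig) into regions
    n_reg <- 0L
    for (ctg in unique(wins$contig)) {
      e <- elev[wins$contig == ctg]
      st <- wins$first[wins$contig == ctg]
      if (!any(e)) next
      idx <- which(e)
      gaps <- which(diff(st[idx]) >= cfg$fst_window)  # disjoint windows
      n_reg <- n_reg + length(gaps) + 1L
    }
    regions[j] <- n_reg
  }
  wins$first <- NULL
  list(windows = wins, regions = regions,
       genome_mean = genome_mean, genome_sd = genome_sd)
}

#' Filter genes eligible for the F_ST scan
#'
#' Keeps genes with a complete start and stop codon (standard start codons
#' ATG/GTG/TTG, standard stops) and mean coverage within 2 standard
#' deviations of the genome mean coverage in both samples.
#'
#' @param genes gene-model data.frame.
#' @param sequences named character vector of contig sequences.
#' @param coverage coverage data.frame (`gene_id, sample, mean_coverage`)
#'   restricted to the two samples of the comparison, or `NULL` to skip the
#'   coverage filter.
#' @return character vector of eligible gene ids.
#' @export
eligible_fst_genes <- function(genes, sequences, coverage = NULL) {
  ok <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    seq <- substr(sequences[[g$contig]], g$start + 1, g$end)
    if (nchar(seq) %% 3 != 0) return(FALSE)
    if (g$strand == "-") seq <- revcomp(seq)
    first <- substr(seq, 1, 3)
    last <- substr(seq, nchar(seq) - 2, nchar(seq))
    first %in% c("ATG", "GTG", "TTG") && last %in% c("TAA", "TAG", "TGA")
  }, logical(1))
  ids <- genes$gene_id[ok]
  if (!is.null(coverage)) {
    cm <- tapply(coverage$mean_coverage, coverage$gene_id, mean)
    mu <- mean(cm); s <- sd(cm)
    in_band <- names(cm)[abs(cm - mu) <= 2 * s | s == 0]
    ids <- intersect(ids, in_band)
  }
  ids
}

#' Gene frequency (copies per genome) from coverage ratios
#'
#' Divides each gene's coverage by the median gene coverage of its sample,
#' yielding copies per genome (1 = single chromosomal copy). Genes on
#' contigs shorter than `cfg$min_contig_len` are excluded. Variable genes
#' are those whose frequency range (max - min over the time points of
#' interest) is at least `cfg$genefreq_delta`.
#'
#' @param coverage coverage data.frame (`gene_id, sample, mean_coverage`).
#' @param genes gene-model data.frame (with `contig_length` populated), or
#'   `NULL` to skip the contig-length filter.
#' @param toi time points of interest; defaults to all samples present.
#' @param cfg an [run_config()] object.
#' @return list: `frequencies` (gene x sample matrix), `variable_genes`
#'   (character vector), `cluster_order` (display order of variable genes).
#' @export
gene_frequency <- function(coverage, genes = NULL, toi = NULL,
                           cfg = run_config()) {
  if (!is.null(genes)) {
    keep <- genes$gene_id[is.na(genes$contig_length) |
                            genes$contig_length >= cfg$min_contig_len]
    coverage <- coverage[coverage$gene_id %in% keep, , drop = FALSE]
  }
  samples <- unique(coverage$sample)
  toi <- toi %||% samples
  gene_ids <- unique(coverage$gene_id)
  m <- matrix(NA_real_, length(gene_ids), length(samples),
              dimnames = list(gene_ids, samples))
  m[cbind(coverage$gene_id, coverage$sample)] <- coverage$mean_coverage
  med <- apply(m, 2, median, na.rm = TRUE)
  if (any(med == 0, na.rm = TRUE))
    stop("gene_frequency: zero median coverage (degenerate sample)")
  freq <- sweep(m, 2, med, "/")
  sub <- freq[, toi, drop = FALSE]
  rng <- apply(sub, 1, function(x) diff(range(x, na.rm = TRUE)))
  variable <- rownames(freq)[rng >= cfg$genefreq_delta]
  ord <- variable
  if (length(variable) >= 3) {
    vm <- sub[variable, , drop = FALSE]
    ok <- rowSums(is.na(vm)) == 0
    if (sum(ok) >= 3) {
      hc <- hclust(dist(vm[ok, , drop = FALSE]), method = "average")
      ord <- c(variable[ok][hc$order], variable[!ok])
    }
  }
  list(frequencies = freq, variable_genes = variable, cluster_order = ord)
}

# Half-up integer percent, matching printed-report rounding (0.571 -> 1).
percent_half_up <- function(count, total) {
  if (total == 0) return(0L)
  as.integer(floor(100 * count / total + 0.5))
}

#' Per-MAG sweep summary report
#'
#' Combines the sweep scan, dN/dS categories and F_ST region counts into a
#' per-population report row: total CDS, count and half-up-rounded percent
#' of low-diversity CDS, the dN/dS category breakdown of those CDS (percent
#' of low-diversity CDS), the longest consecutive low-diversity run, and
#' elevated-F_ST region counts at 1 and 2 SD.
#'
#' @param mag MAG identifier.
#' @param total_cds total number of coding sequences.
#' @param sweep_calls data.frame from [low_diversity_genes()].
#' @param dnds_categories named character vector gene_id -> category
#'   (`"below_genome_mean"`, `"relaxed"`, `"none"`) for flagged genes;
#'   genes absent from the vector count as `"none"`.
#' @param fst_regions named integer vector of region counts (from
#'   [window_fst_scan()]`$regions`), or `NULL` for zeros.
#' @return one-row data.frame shaped like a per-genome sweep table.
#' @export
summarize_sweep_report <- function(mag, total_cds, sweep_calls,
                                   dnds_categories = NULL,
                                   fst_regions = NULL) {
  flagged <- sweep_calls$gene_id[sweep_calls$flagged]
  n_low <- length(flagged)
  cat_of <- function(g) {
    if (is.null(dnds_categories) || !g %in% names(dnds_categories)) "none"
    else dnds_categories[[g]]
  }
  cats <- vapply(flagged, cat_of, "")
  n_below <- sum(cats == "below_genome_mean")
  n_relax <- sum(cats == "relaxed")
  n_none <- sum(cats == "none")
  longest <- if (n_low) max(sweep_calls$run_length, na.rm = TRUE) else 0L
  fst_regions <- fst_regions %||% c(sd1 = 0L, sd2 = 0L)
  data.frame(
    mag = mag,
    n_cds = total_cds,
    n_low_pi = n_low,
    pct_low_pi = percent_half_up(n_low, total_cds),
    n_low_dnds = n_below,
    pct_low_dnds = percent_half_up(n_below, n_low),
    n_relaxed_dnds = n_relax,
    pct_relaxed_dnds = percent_half_up(n_relax, n_low),
    n_no_dnds = n_none,
    pct_no_dnds = percent_half_up(n_none, n_low),
    longest_low_pi_run = longest,
    fst_regions_1sd = unname(fst_regions["sd1"]),
    fst_regions_2sd = unname(fst_regions["sd2"])
  )
}
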