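# SNV calling and nucleotide diversity from per-site allele counts.

count_matrix <- function(sites) {
  m <- as.matrix(sites[, NUCS])
  storage.mode(m) <- "double"
  m
}

# Count-maximal nucleotide; ties broken in fixed order A < C < G < T.
major_allele_idx <- function(m) max.col(m, ties.method = "first")

#' Major allele frequency of a site
#'
#' The consensus (major) allele is the count-maximal nucleotide — the
#' reference base plays no role. Ties are broken in the fixed order
#' A < C < G < T for determinism.
#'
#' @param sites allele-count data.frame (columns `A,C,G,T`; other columns
#'   are carried through untouched).
#' @return data.frame `sites` with added columns `coverage`, `major_allele`,
#'   `major_allele_frequency`.
#' @export
#' @examples
#' s <- data.frame(contig = "c", position = 0L, sample = "TP1", ref = "G",
#'                 A = 90L, C = 10L, G = 0L, T = 0L)
#' major_allele_frequency(s)$major_allele_frequency  # 0.9, major A
major_allele_frequency <- function(sites) {
  m <- count_matrix(sites)
  cov <- rowSums(m)
  if (any(cov == 0))
    stop("major_allele_frequency: zero coverage site")
  idx <- major_allele_idx(m)
  sites$coverage <- cov
  sites$major_allele <- NUCS[idx]
  sites$major_allele_frequency <- m[cbind(seq_len(nrow(m)), idx)] / cov
  sites
}

# Shannon entropy (bits) of the count-frequency distribution per site.
site_entropy <- function(m) {
  cov <- rowSums(m)
  p <- m / ifelse(cov == 0, 1, cov)
  lp <- ifelse(p > 0, log2(p), 0)
  -rowSums(p * lp)
}

#' Call SNVs from allele counts
#'
#' A site is an SNV iff its count entropy is > 0, its coverage is at least
#' `cfg$min_coverage`, and the departure from consensus (1 - major allele
#' frequency) is at least `cfg$min_departure`. Zero-coverage sites are
#' silently skipped.
#'
#' @param sites allele-count data.frame.
#' @param cfg an [run_config()] object.
#' @return data.frame of SNV records: the input columns plus `coverage`,
#'   `major_allele`, `major_allele_frequency`, `departure_from_consensus`,
#'   `entropy`.
#' @export
call_snvs <- function(sites, cfg = run_config()) {
  check_columns(sites, c("contig", "position", "sample", NUCS), "allele counts")
  m <- count_matrix(sites)
  cov <- rowSums(m)
  sites <- sites[cov > 0, , drop = FALSE]
  m <- m[cov > 0, , drop = FALSE]
  sites <- major_allele_frequency(sites)
  sites$departure_from_consensus <- 1 - sites$major_allele_frequency
  sites$entropy <- site_entropy(m)
  keep <- sites$entropy > 0 &
    sites$coverage >= cfg$min_coverage &
    sites$departure_from_consensus >= cfg$min_departure
  sites[keep, , drop = FALSE]
}

#' SNV density in SNVs per kilobase pair
#'
#' @param snv_count number of SNVs.
#' @param mag_length MAG length in bp (full length, not just covered).
#' @return SNVs per kbp.
#' @export
snv_density <- function(snv_count, mag_length) {
  if (any(mag_length <= 0)) stop("snv_density: mag_length must be > 0")
  snv_count / (mag_length / 1e3)
}

#' Per-site nucleotide diversity
#'
#' The probability that two reads drawn without replacement from a site
#' carry different nucleotides: `1 - sum_i c_i (c_i - 1) / (n (n - 1))`.
#' This is the unbiased (n-choose-2) estimator; sites with coverage < 2 are
#' undefined and returned as `NA`.
#'
#' @param sites allele-count data.frame, or a numeric count matrix with
#'   columns A,C,G,T.
#' @return numeric vector of per-site pi.
#' @export
#' @examples
#' site_pi(matrix(c(10, 10, 0, 0), 1, dimnames = list(NULL, c("A","C","G","T"))))
site_pi <- function(sites) {
  m <- if (is.matrix(sites)) sites else count_matrix(sites)
  n <- rowSums(m)
  pi <- 1 - rowSums(m * (m - 1)) / (n * (n - 1))
  pi[n < 2] <- NA_real_
  pi
}

#' Mean nucleotide diversity over a region
#'
#' Averages per-site pi over all covered positions of a gene or genome.
#' Invariant covered positions contribute 0, so when the allele-count table
#' only stores variable sites, pass the total number of covered positions as
#' `n_covered`.
#'
#' @param pi_values per-site pi at the variable (stored) sites; `NA`s are
#'   dropped as uncovered.
#' @param n_covered total number of positions with sufficient coverage
#'   (defaults to `length(pi_values)` after `NA` removal).
#' @return mean pi, or `NA` if no covered site.
#' @export
mean_pi <- function(pi_values, n_covered = NULL) {
  pi_values <- pi_values[!is.na(pi_values)]
  n_covered <- n_covered %||% length(pi_values)
  if (n_covered < 1) return(NA_real_)
  sum(pi_values) / n_covered
}

#' Expand stored-site pi values to a full per-site vector
#'
#' Pads `n_covered - length(pi_values)` zeros for the invariant covered
#' positions, producing the per-site sample a Welch comparison needs.
#'
#' @inheritParams mean_pi
#' @return numeric vector of length `n_covered`.
#' @export
expand_pi_sites <- function(pi_values, n_covered) {
  pi_values <- pi_values[!is.na(pi_values)]
  if (n_covered < length(pi_values))
    stop("expand_pi_sites: n_covered smaller than number of stored sites")
  c(pi_values, numeric(n_covered - length(pi_values)))
}

#' Per-sample diversity summary for one MAG
#'
#' @param sites allele-count data.frame for one MAG (all samples).
#' @param mag_length MAG length in bp.
#' @param cfg an [run_config()] object.
#' @return data.frame, one row per sample: `sample, snv_count, snv_density,
#'   mean_major_allele_frequency, genome_pi` (genome pi averaged over stored
#'   covered sites; see [mean_pi()] for invariant-site handling).
#' @export
diversity_summary <- function(sites, mag_length, cfg = run_config()) {
  samples <- unique(sites$sample)
  rows <- lapply(samples, function(sm) {
    s <- sites[sites$sample == sm, , drop = FALSE]
    snvs <- call_snvs(s, cfg)
    covered <- s[rowSums(count_matrix(s)) >= cfg$min_coverage, , drop = FALSE]
    data.frame(
      sample = sm,
      snv_count = nrow(snvs),
      snv_density = snv_density(nrow(snvs), mag_length),
      mean_major_allele_frequency =
        if (nrow(snvs)) mean(snvs$major_allele_frequency) else NA_real_,
      genome_pi = mean_pi(site_pi(covered))
    )
  })
  do.call(rbind, rows)
}

#' Major-allele-frequency matrix across time points of interest
#'
#' Rows are the union of SNV positions over the time points of interest; the
#' tracked allele of a row is the consensus at the first toi where the site
#' is an SNV, so a row's trajectory is comparable across columns. Cells
#' where the site is an SNV hold the tracked-allele frequency; positions
#' covered at >= `min_coverage` but not called are assumed fixed at the
#' consensus (value 1.0); cells below `min_coverage` are masked (`NA`).
#'
#' @param sites allele-count data.frame (all samples of one MAG).
#' @param toi character vector of time points of interest, chronological.
#' @param cfg an [run_config()] object.
#' @return numeric matrix (positions x toi) with rownames `contig:position`
#'   (1-based report coordinates) and attributes `tracked_allele` and
#'   `cluster_order` (average-linkage Euclidean ordering for display).
#' @export
build_allele_matrix <- function(sites, toi, cfg = run_config()) {
  stopifnot(length(toi) >= 1)
  snv_by_tp <- lapply(toi, function(tp)
    call_snvs(sites[sites$sample == tp, , drop = FALSE], cfg))
  names(snv_by_tp) <- toi
  keys <- unique(unlist(lapply(snv_by_tp, function(s)
    paste(s$contig, s$position))))
  if (!length(keys))
    return(matrix(numeric(), 0, length(toi), dimnames = list(NULL, toi)))

  tracked <- setNames(rep(NA_character_, length(keys)), keys)
  for (tp in toi) {
    s <- snv_by_tp[[tp]]
    k <- paste(s$contig, s$position)
    new <- is.na(tracked[k])
    tracked[k[new]] <- s$major_allele[new]
  }

  mat <- matrix(NA_real_, length(keys), length(toi),
                dimnames = list(keys, toi))
  for (tp in toi) {
    s <- sites[sites$sample == tp, , drop = FALSE]
    k <- paste(s$contig, s$position)
    idx <- match(keys, k)
    present <- !is.na(idx)
    sm <- count_matrix(s)[idx[present], , drop = FALSE]
    cov <- rowSums(sm)
    snv_keys <- paste(snv_by_tp[[tp]]$contig, snv_by_tp[[tp]]$position)
    is_snv <- keys[present] %in% snv_keys
    val <- rep(NA_real_, sum(present))
    tr <- match(tracked[keys[present]], NUCS)
    freq <- sm[cbind(seq_len(nrow(sm)), tr)] / cov
    val[is_snv] <- freq[is_snv]
    val[!is_snv & cov >= cfg$min_coverage] <- 1.0
    mat[present, tp] <- val
  }

  parts <- strsplit(keys, " ")
  rownames(mat) <- vapply(parts, function(p)
    sprintf("%s:%d", p[1], to_report_position(as.integer(p[2]))), "")
  attr(mat, "tracked_allele") <- setNames(unname(tracked), rownames(mat))
  attr(mat, "cluster_order") <- allele_matrix_order(mat)
  mat
}

# Average-linkage Euclidean hierarchical clustering order for display;
# rows with masked cells are ordered last, untouched.
allele_matrix_order <- function(mat) {
  ok <- which(rowSums(is.na(mat)) == 0)
  if (length(ok) < 3) return(seq_len(nrow(mat)))
  hc <- hclust(dist(mat[ok, , drop = FALSE], method = "euclidean"),
               method = "average")
  c(ok[hc$order], setdiff(seq_len(nrow(mat)), ok))
}
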