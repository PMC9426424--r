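# Focal-population selection from MAG abundance.

#' Reads per kilobase MAG per megabase of sample (RPKM)
#'
#' Normalizes a mapped-read count by MAG length (kbp) and total base pairs
#' sequenced in the sample (Mbp):
#' `RPKM = reads / ((mag_length/1e3) * (sample_size/1e6))`.
#'
#' @param mapped_reads number of reads recruited to the MAG (vectorized).
#' @param mag_length MAG length in bp.
#' @param sample_size total bp sequenced in the sample.
#' @return RPKM value(s).
#' @export
#' @examples
#' compute_rpkm(1000, 2e6, 1e9)  # 0.5
compute_rpkm <- function(mapped_reads, mag_length, sample_size) {
  if (any(mag_length <= 0)) stop("compute_rpkm: mag_length must be > 0")
  if (any(sample_size <= 0)) stop("compute_rpkm: sample_size must be > 0")
  mapped_reads / ((mag_length / 1e3) * (sample_size / 1e6))
}

#' Build a MAG-by-sample RPKM matrix
#'
#' @param abundance long data.frame with columns `mag, sample, mapped_reads`.
#' @param mag_lengths named vector of MAG lengths (bp).
#' @param sample_sizes named vector of total bp sequenced per sample; sample
#'   (column) order is taken from this vector and must be chronological.
#' @return numeric matrix, MAGs as rows, samples as columns (chronological).
#' @export
abundance_matrix <- function(abundance, mag_lengths, sample_sizes) {
  check_columns(abundance, ABUNDANCE_COLS, "abundance table")
  mags <- unique(abundance$mag)
  samples <- names(sample_sizes)
  m <- matrix(0, length(mags), length(samples),
              dimnames = list(mags, samples))
  rpkm <- compute_rpkm(abundance$mapped_reads,
                       mag_lengths[abundance$mag],
                       sample_sizes[abundance$sample])
  m[cbind(abundance$mag, abundance$sample)] <- rpkm
  m
}

#' Select focal populations from an RPKM matrix
#'
#' Two inclusive criteria: (i) *persistent* populations have RPKM >=
#' `min_rpkm_toi` in at least `min_toi_count` samples; (ii) *spike*
#' populations fail (i) but reach RPKM >= `rpkm_spike` in at least one
#' sample. Time points of interest (toi) per population are the samples at
#' RPKM >= `min_rpkm_toi`, in chronological (column) order.
#'
#' @param rpkm numeric MAG-by-sample matrix with chronological columns.
#' @param cfg an [run_config()] object.
#' @return list of class `focal_selection`: `persistent_mags`, `spike_mags`
#'   (character vectors) and `toi` (named list of sample vectors).
#' @export
select_focal_mags <- function(rpkm, cfg = run_config()) {
  stopifnot(is.matrix(rpkm), nrow(rpkm) > 0)
  hits <- rpkm >= cfg$min_rpkm_toi
  persistent <- rowSums(hits) >= cfg$min_toi_count
  spike <- !persistent & apply(rpkm >= cfg$rpkm_spike, 1, any)
  toi <- lapply(rownames(rpkm), function(m) colnames(rpkm)[hits[m, ]])
  names(toi) <- rownames(rpkm)
  structure(list(persistent_mags = rownames(rpkm)[persistent],
                 spike_mags = rownames(rpkm)[spike],
                 toi = toi),
            class = "focal_selection")
}

#' @export
print.focal_selection <- function(x, ...) {
  cat("Focal population selection\n")
  cat("  persistent:", paste(x$persistent_mags, collapse = ", "), "\n")
  cat("  spike:     ", paste(x$spike_mags, collapse = ", "), "\n")
  invisible(x)
}

#' Time points of interest for one MAG
#'
#' @param rpkm MAG-by-sample RPKM matrix.
#' @param mag MAG identifier (must be a row of `rpkm`).
#' @param cfg an [run_config()] object.
#' @return character vector of sample names with RPKM >= `min_rpkm_toi`, in
#'   chronological order.
#' @export
time_points_of_interest <- function(rpkm, mag, cfg = run_config()) {
  if (!mag %in% rownames(rpkm))
    stop("time_points_of_interest: unknown MAG '", mag, "'")
  colnames(rpkm)[rpkm[mag, ] >= cfg$min_rpkm_toi]
}
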