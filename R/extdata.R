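# Bundled worked-example tables (printed study data, plain TSV).

#' Bundled MAG abundance matrix (worked example)
#'
#' The published 10-MAG-by-10-time-point RPKM matrix from a 2-year
#' subseafloor crustal fluid time series, shipped as a worked example for
#' [select_focal_mags()].
#'
#' @return numeric matrix (MAGs x time points).
#' @export
norp_rpkm_matrix <- function() {
  df <- read_tsv(system.file("extdata", "norp_rpkm_table.tsv",
                             package = "aquiferpop"))
  m <- as.matrix(df[, -1])
  rownames(m) <- df$mag
  m
}

#' Bundled per-genome sweep counts (worked example)
#'
#' Published per-genome counts of coding sequences, low-nucleotide-diversity
#' coding sequences, their dN/dS category breakdown, the longest consecutive
#' low-diversity run and elevated-F_ST region counts; used to exercise the
#' report arithmetic of [summarize_sweep_report()].
#'
#' @return data.frame.
#' @export
norp_sweep_counts <- function() {
  read_tsv(system.file("extdata", "norp_sweep_counts.tsv",
                       package = "aquiferpop"))
}
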