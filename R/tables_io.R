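# Readers/writers for the project table formats. All tables travel as plain
# data.frames; column layouts are fixed so every writer/reader pair is a
# lossless inverse on valid data.

ALLELE_COLS  <- c("contig", "position", "sample", "ref", "A", "C", "G", "T")
LINKAGE_COLS <- c("contig", "pos_a", "pos_b", "sample",
                  "allele_A", "allele_a", "allele_B", "allele_b",
                  "n_AB", "n_Ab", "n_aB", "n_ab")
COVERAGE_COLS <- c("gene_id", "sample", "mean_coverage")
ABUNDANCE_COLS <- c("mag", "sample", "mapped_reads")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

read_tsv <- function(path) {
  data.table::setDF(data.table::fread(path, sep = "\t", header = TRUE,
                                      colClasses = NULL, showProgress = FALSE))
}

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read and write per-site allele count tables
#'
#' The allele-count table is the atomic observation of the pipeline: one row
#' per (contig, position, sample) carrying the A/C/G/T read counts and the
#' reference base. Positions are stored 0-based.
#'
#' @param path TSV file with header columns
#'   `contig, position, sample, ref, A, C, G, T`.
#' @return a data.frame with those columns; counts as integers.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' x <- data.frame(contig = "c1", position = 10L, sample = "TP1", ref = "A",
#'                 A = 18L, C = 2L, G = 0L, T = 0L)
#' write_allele_counts(x, tf)
#' read_allele_counts(tf)
read_allele_counts <- function(path) {
  df <- read_tsv(path)
  check_columns(df, ALLELE_COLS, "allele count table")
  df <- df[, ALLELE_COLS]
  df$position <- as.integer(df$position)
  for (n in NUCS) df[[n]] <- as.integer(df[[n]])
  neg <- which(df$A < 0 | df$C < 0 | df$G < 0 | df$T < 0)
  if (length(neg))
    stop(sprintf("allele count table: negative count at row %d", neg[1]))
  df
}

#' @rdname read_allele_counts
#' @param sites allele-count data.frame.
#' @export
write_allele_counts <- function(sites, path) {
  check_columns(sites, ALLELE_COLS, "allele count table")
  write_tsv(sites[, ALLELE_COLS], path)
}

#' Read and write read-linked SNV pair tables
#'
#' One row per pair of biallelic sites observed on the same read or read
#' pair, in one sample. `allele_A`/`allele_a` are the two nucleotides at
#' `pos_a`, `allele_B`/`allele_b` those at `pos_b`; `n_AB` .. `n_ab` count
#' the four two-locus haplotypes among spanning read pairs.
#'
#' @param path TSV with the columns listed above.
#' @return data.frame; haplotype counts as integers.
#' @export
read_linkage_table <- function(path) {
  df <- read_tsv(path)
  check_columns(df, LINKAGE_COLS, "linkage table")
  df <- df[, LINKAGE_COLS]
  df$pos_a <- as.integer(df$pos_a)
  df$pos_b <- as.integer(df$pos_b)
  for (n in c("n_AB", "n_Ab", "n_aB", "n_ab")) df[[n]] <- as.integer(df[[n]])
  tot <- df$n_AB + df$n_Ab + df$n_aB + df$n_ab
  if (any(tot < 1))
    stop(sprintf("linkage table: all-zero haplotype counts at row %d",
                 which(tot < 1)[1]))
  if (any(df$pos_a == df$pos_b))
    stop("linkage table: zero distance pair (pos_a == pos_b)")
  df
}

#' @rdname read_linkage_table
#' @param pairs linkage data.frame.
#' @export
write_linkage_table <- function(pairs, path) {
  check_columns(pairs, LINKAGE_COLS, "linkage table")
  write_tsv(pairs[, LINKAGE_COLS], path)
}

#' Read and write per-gene coverage tables
#'
#' @param path TSV with columns `gene_id, sample, mean_coverage`.
#' @return data.frame.
#' @export
read_coverage_table <- function(path) {
  df <- read_tsv(path)
  check_columns(df, COVERAGE_COLS, "coverage table")
  df <- df[, COVERAGE_COLS]
  if (any(df$mean_coverage < 0))
    stop("coverage table: negative coverage")
  df
}

#' @rdname read_coverage_table
#' @param coverage coverage data.frame.
#' @export
write_coverage_table <- function(coverage, path) {
  check_columns(coverage, COVERAGE_COLS, "coverage table")
  write_tsv(coverage[, COVERAGE_COLS], path)
}

#' Read a MAG-by-sample mapped read count table
#'
#' @param path TSV with columns `mag, sample, mapped_reads`.
#' @return data.frame.
#' @export
read_abundance_table <- function(path) {
  df <- read_tsv(path)
  check_columns(df, ABUNDANCE_COLS, "abundance table")
  df[, ABUNDANCE_COLS]
}

#' Read gene models from GFF3
#'
#' Coordinates are converted from the 1-based inclusive GFF3 convention to
#' the internal 0-based half-open convention. The gene identifier is taken
#' from the `ID` attribute.
#'
#' @param path GFF3 file (e.g. Prodigal gene predictions).
#' @param contig_lengths optional named vector of contig lengths (bp) used to
#'   populate the `contig_length` column; `NA` otherwise.
#' @return data.frame with columns `gene_id, contig, start, end, strand,
#'   contig_length` (`start`/`end` 0-based half-open).
#' @export
read_gff3 <- function(path, contig_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0)
    return(data.frame(gene_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), contig_length = integer()))
  strands <- as.character(GenomicRanges::strand(gr))
  if (any(!strands %in% c("+", "-")))
    stop("read_gff3: unknown strand symbol '",
         strands[!strands %in% c("+", "-")][1], "'")
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids))
    stop("read_gff3: feature without an ID attribute")
  contigs <- as.character(GenomicRanges::seqnames(gr))
  out <- data.frame(
    gene_id = as.character(ids),
    contig = contigs,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strands,
    contig_length = if (is.null(contig_lengths)) NA_integer_ else
      as.integer(contig_lengths[contigs]),
    stringsAsFactors = FALSE
  )
  bad <- out$start >= out$end
  if (any(bad))
    stop("read_gff3: end before start for feature ", out$gene_id[bad][1])
  out
}

#' Write gene models to GFF3 (inverse of [read_gff3()])
#'
#' @param genes gene-model data.frame with 0-based half-open coordinates.
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  check_columns(genes, c("gene_id", "contig", "start", "end", "strand"),
                "gene models")
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "CDS"
  gr$source <- "aquiferpop"
  gr$phase <- 0L
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' Sequences are uppercased; identifiers are the first whitespace-delimited
#' token of the header. Duplicate identifiers are an error.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("read_fasta: duplicate identifier '", ids[duplicated(ids)][1], "'")
  setNames(toupper(as.character(ss)), ids)
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  names(ss) <- names(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Cross-validate an input bundle
#'
#' Checks referential integrity across whatever subset of inputs is given:
#' allele-count sites must fall on known contigs within bounds, linkage pairs
#' must reference known sites and be biallelic at both ends, gene intervals
#' must lie within their contig. Returns a report rather than erroring; an
#' empty report means the bundle is consistent.
#'
#' @param sites allele-count data.frame, or `NULL`.
#' @param genes gene-model data.frame, or `NULL`.
#' @param pairs linkage data.frame, or `NULL`.
#' @param sequences named character vector of contig sequences, or `NULL`.
#' @return data.frame with columns `component, message`; zero rows if valid.
#' @export
validate_bundle <- function(sites = NULL, genes = NULL, pairs = NULL,
                            sequences = NULL) {
  v <- list()
  note <- function(component, message)
    v[[length(v) + 1L]] <<- data.frame(component = component,
                                       message = message)
  if (!is.null(sites) && !is.null(sequences)) {
    unknown <- !(sites$contig %in% names(sequences))
    for (i in which(unknown))
      note("sites", sprintf("site %s:%d on unknown contig",
                            sites$contig[i], sites$position[i]))
    known <- which(!unknown)
    lens <- nchar(sequences)[sites$contig[known]]
    over <- known[sites$position[known] >= lens]
    for (i in over)
      note("sites", sprintf("site %s:%d beyond contig end",
                            sites$contig[i], sites$position[i]))
  }
  if (!is.null(pairs) && !is.null(sites)) {
    key <- paste(sites$contig, sites$position)
    for (i in seq_len(nrow(pairs))) {
      for (p in c(pairs$pos_a[i], pairs$pos_b[i])) {
        if (!(paste(pairs$contig[i], p) %in% key))
          note("pairs", sprintf("pair references unknown site %s:%d",
                                pairs$contig[i], p))
      }
    }
    # multi-allelic sites are excluded from linkage by design; flag them
    n_alleles <- rowSums(as.matrix(sites[, NUCS]) > 0)
    multi <- key[n_alleles > 2]
    for (i in seq_len(nrow(pairs))) {
      for (p in c(pairs$pos_a[i], pairs$pos_b[i])) {
        if (paste(pairs$contig[i], p) %in% multi)
          note("pairs", sprintf("pair references multi-allelic site %s:%d",
                                pairs$contig[i], p))
      }
    }
  }
  if (!is.null(genes) && !is.null(sequences)) {
    unknown <- !(genes$contig %in% names(sequences))
    for (i in which(unknown))
      note("genes", sprintf("gene %s on unknown contig", genes$gene_id[i]))
    known <- which(!unknown)
    lens <- nchar(sequences)[genes$contig[known]]
    over <- known[genes$end[known] > lens]
    for (i in over)
      note("genes", sprintf("gene %s overruns contig end", genes$gene_id[i]))
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(component = character(), message = character())
}
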