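# Haplotype QC and pairwise Nei-Gojobori (1986) dN/dS with
# Jukes-Cantor correction.

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

translate_dna <- function(seq) {
  codons <- substring(seq, seq(1, nchar(seq) - 2, 3), seq(3, nchar(seq), 3))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

#' Quality-control gene haplotypes
#'
#' Orients minus-strand haplotypes by reverse complementing, drops
#' haplotypes whose length is not a multiple of 3, trims a terminal stop
#' codon, drops haplotypes translating with an internal stop, and collapses
#' exact duplicates to one representative (time points of origin are
#' merged).
#'
#' @param haplotypes named character vector of nucleotide haplotypes for one
#'   gene (names are haplotype ids).
#' @param strand `"+"` or `"-"`: the gene's strand; minus-strand input is
#'   reverse complemented.
#' @param time_points optional character vector (same length) of the time
#'   point each haplotype was observed in.
#' @return list of class `haplotype_set`: `sequences` (named character
#'   vector, deduplicated, stop-trimmed), `isoforms` (translations),
#'   `time_points` (list per retained haplotype), `dropped` (data.frame
#'   `id, reason`).
#' @export
qc_haplotypes <- function(haplotypes, strand = "+", time_points = NULL) {
  stopifnot(strand %in% c("+", "-"))
  ids <- names(haplotypes) %||% paste0("hap", seq_along(haplotypes))
  tps <- time_points %||% rep(NA_character_, length(haplotypes))
  dropped <- list()
  keep_seq <- character(); keep_tp <- list()
  for (i in seq_along(haplotypes)) {
    s <- toupper(haplotypes[[i]])
    if (strand == "-") s <- revcomp(s)
    if (nchar(s) %% 3 != 0) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(id = ids[i], reason = "length not divisible by 3")
      next
    }
    aa <- translate_dna(s)
    if (endsWith(aa, "*")) {
      s <- substr(s, 1, nchar(s) - 3)
      aa <- substr(aa, 1, nchar(aa) - 1)
    }
    if (grepl("*", aa, fixed = TRUE)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(id = ids[i], reason = "internal stop codon")
      next
    }
    dup <- match(s, keep_seq)
    if (!is.na(dup)) {
      keep_tp[[dup]] <- unique(c(keep_tp[[dup]], tps[i]))
      next
    }
    keep_seq <- c(keep_seq, setNames(s, ids[i]))
    keep_tp[[length(keep_tp) + 1L]] <- tps[i]
  }
  structure(list(
    sequences = keep_seq,
    isoforms = vapply(keep_seq, translate_dna, ""),
    time_points = keep_tp,
    dropped = if (length(dropped)) do.call(rbind, dropped) else
      data.frame(id = character(), reason = character())
  ), class = "haplotype_set")
}

# --- Nei-Gojobori 1986 machinery ------------------------------------------

# Potential synonymous site count of one codon. At each position the three
# alternative nucleotides are considered; changes producing a stop codon are
# excluded from both numerator and denominator. N sites are 3 - S so that
# S + N = 3 per codon.
ng86_codon_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[[codon]]
  s <- 0
  for (p in 1:3) {
    syn <- 0L; tot <- 0L
    for (nt in setdiff(NUCS, substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- nt
      if (code[[alt]] == "*") next
      tot <- tot + 1L
      if (code[[alt]] == aa) syn <- syn + 1L
    }
    if (tot > 0) s <- s + syn / tot
  }
  s
}

# Observed synonymous/nonsynonymous differences between two codons, averaged
# over all shortest mutational pathways; pathways passing through a stop
# codon are excluded (fallback to all pathways if none is stop-free).
ng86_codon_diffs <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  paths <- if (k == 1) list(pos) else
    lapply(asplit(permutations(pos), 1), as.integer)
  step_counts <- function(order) {
    cur <- c1
    sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[[nxt]] == "*") return(NULL)
      if (code[[cur]] == code[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- lapply(paths, step_counts)
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) {            # every path passes a stop: count all paths
    res <- lapply(paths, function(order) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (code[[cur]] == code[[nxt]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    })
    ok <- rep(TRUE, length(res))
  }
  colMeans(do.call(rbind, res[ok]))
}

permutations <- function(v) {
  if (length(v) == 1) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], permutations(v[-i])))
  out
}

jukes_cantor <- function(p) {
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise dN and dS by the Nei--Gojobori (1986) counting method
#'
#' Counts potential synonymous (S) and nonsynonymous (N) sites per sequence
#' (averaged between the pair), resolves observed codon differences by
#' averaging over all shortest mutational pathways (stop-codon pathways
#' excluded), and corrects the proportions with the Jukes-Cantor formula
#' `d = -3/4 log(1 - 4p/3)`.
#'
#' @param h1,h2 nucleotide sequences of equal length, divisible by 3,
#'   without stop codons.
#' @return named numeric vector: `dN, dS, pN, pS, N, S, Nd, Sd`. `dN`/`dS`
#'   are `NA` when the Jukes-Cantor correction is undefined (p >= 3/4).
#' @export
#' @examples
#' ng86_pair("TTTGCT", "TTCGCT")["dN"]  # 0: TTT->TTC is synonymous
ng86_pair <- function(h1, h2) {
  h1 <- toupper(h1); h2 <- toupper(h2)
  if (nchar(h1) != nchar(h2)) stop("ng86_pair: unequal lengths")
  if (nchar(h1) %% 3 != 0) stop("ng86_pair: length not divisible by 3")
  n_codons <- nchar(h1) / 3
  starts <- seq(1, nchar(h1) - 2, 3)
  cod1 <- substring(h1, starts, starts + 2)
  cod2 <- substring(h2, starts, starts + 2)
  if (any(Biostrings::GENETIC_CODE[cod1] == "*") ||
      any(Biostrings::GENETIC_CODE[cod2] == "*"))
    stop("ng86_pair: sequence contains a stop codon")
  S1 <- sum(vapply(cod1, ng86_codon_sites, 0))
  S2 <- sum(vapply(cod2, ng86_codon_sites, 0))
  S <- (S1 + S2) / 2
  N <- 3 * n_codons - S
  d <- vapply(seq_len(n_codons), function(i)
    ng86_codon_diffs(cod1[i], cod2[i]), c(sd = 0, nd = 0))
  Sd <- sum(d["sd", ])
  Nd <- sum(d["nd", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  c(dN = jukes_cantor(pN), dS = jukes_cantor(pS),
    pN = pN, pS = pS, N = N, S = S, Nd = Nd, Sd = Sd)
}

#' Per-gene dN/dS summary over all haplotype pairs
#'
#' Computes Nei-Gojobori dN and dS for every pair of retained haplotypes,
#' keeps pairs with `dN > cfg$dn_min`, `cfg$ds_range[1] < dS <
#' cfg$ds_range[2]` and `dN/dS < cfg$dnds_max`, and averages dN/dS and dS
#' over the retained pairs.
#'
#' @param haps a `haplotype_set` from [qc_haplotypes()] (or a named
#'   character vector of QCed haplotypes).
#' @param cfg an [run_config()] object.
#' @return one-row data.frame: `n_haplotypes, n_pairs, n_retained,
#'   mean_dnds, mean_ds` (`NA` means when nothing retained).
#' @export
gene_dnds_summary <- function(haps, cfg = run_config()) {
  seqs <- if (inherits(haps, "haplotype_set")) haps$sequences else haps
  empty <- data.frame(n_haplotypes = length(seqs), n_pairs = 0L,
                      n_retained = 0L, mean_dnds = NA_real_,
                      mean_ds = NA_real_)
  if (length(seqs) < 2) return(empty)
  idx <- combn(length(seqs), 2)
  res <- apply(idx, 2, function(ij) ng86_pair(seqs[[ij[1]]], seqs[[ij[2]]]))
  dN <- res["dN", ]; dS <- res["dS", ]
  dnds <- ifelse(!is.na(dN) & !is.na(dS) & dS > 0, dN / dS, NA_real_)
  keep <- !is.na(dnds) &
    dN > cfg$dn_min &
    dS > cfg$ds_range[1] & dS < cfg$ds_range[2] &
    dnds < cfg$dnds_max
  if (!any(keep)) {
    empty$n_pairs <- ncol(idx)
    return(empty)
  }
  data.frame(n_haplotypes = length(seqs), n_pairs = ncol(idx),
             n_retained = sum(keep),
             mean_dnds = mean(dnds[keep]), mean_ds = mean(dS[keep]))
}

#' Assign dN/dS selection categories across genes
#'
#' A gene with retained pairs is `below_genome_mean` when its mean dN/dS is
#' below the genome-wide mean of per-gene means, `relaxed` when its mean
#' dN/dS exceeds 1, and `none` when no pair survived the filters. (A gene
#' above the genome mean but below 1 keeps category `below_genome_mean`
#' only if below the mean; otherwise it is left uncategorized as `other`.)
#'
#' @param gene_means named numeric vector gene_id -> mean dN/dS (`NA` for
#'   genes without retained pairs).
#' @param genome_mean `"gene"` (default) uses the mean of per-gene means;
#'   or a numeric value to use directly (e.g. a pair-pooled mean).
#' @return named character vector of categories.
#' @export
dnds_categories <- function(gene_means, genome_mean = "gene") {
  gm <- if (identical(genome_mean, "gene"))
    mean(gene_means, na.rm = TRUE) else genome_mean
  out <- rep("none", length(gene_means))
  names(out) <- names(gene_means)
  has <- !is.na(gene_means)
  out[has & gene_means > 1] <- "relaxed"
  out[has & gene_means <= 1 & gene_means < gm] <- "below_genome_mean"
  out[has & gene_means <= 1 & gene_means >= gm] <- "other"
  out
}
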