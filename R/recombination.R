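# Linkage disequilibrium and four-gamete signals from read-linked SNV pairs.

#' Linkage disequilibrium r-squared for a two-locus haplotype count table
#'
#' With haplotype counts (AB, Ab, aB, ab) summing to n, allele frequencies
#' `f_A = (AB+Ab)/n`, `f_B = (AB+aB)/n` and `D = AB/n - f_A f_B`, returns
#' `r2 = D^2 / (f_A(1-f_A) f_B(1-f_B))`. Undefined (`NA`) when either site
#' is monomorphic within the pair sample.
#'
#' @param pairs linkage data.frame (columns `n_AB, n_Ab, n_aB, n_ab`), or a
#'   numeric vector/matrix of the four counts in that order.
#' @return numeric vector of r2 values in \[0, 1\], `NA` where undefined.
#' @export
#' @examples
#' pair_r2(c(50, 0, 0, 50))            # 1
#' pair_r2(c(25, 25, 25, 25))          # 0
#' pair_r2(c(40, 10, 10, 40))          # 0.36
pair_r2 <- function(pairs) {
  m <- hap_count_matrix(pairs)
  n <- rowSums(m)
  if (any(n < 1)) stop("pair_r2: empty haplotype count table")
  fA <- (m[, 1] + m[, 2]) / n
  fB <- (m[, 1] + m[, 3]) / n
  D <- m[, 1] / n - fA * fB
  den <- fA * (1 - fA) * fB * (1 - fB)
  r2 <- ifelse(den > 0, D^2 / den, NA_real_)
  unname(pmin(pmax(r2, 0), 1))  # clamp float noise at the exact bounds
}

hap_count_matrix <- function(pairs) {
  if (is.data.frame(pairs)) {
    as.matrix(pairs[, c("n_AB", "n_Ab", "n_aB", "n_ab")])
  } else if (is.matrix(pairs)) {
    pairs
  } else {
    matrix(pairs, nrow = 1)
  }
}

#' Four-gamete classification of a linked SNV pair
#'
#' Counts how many of the four two-locus haplotypes are present at a minimum
#' of `presence_threshold` read pairs and returns `"H1"`–`"H4"`. Under the
#' infinite-sites model the fourth haplotype can only arise through
#' homologous recombination, so H4 pairs are the recombination signal.
#'
#' @inheritParams pair_r2
#' @param presence_threshold minimum count for a haplotype to be present.
#' @return character vector of classes `"H1".."H4"`.
#' @export
#' @examples
#' classify_gametes(c(5, 0, 0, 5))     # "H2"
#' classify_gametes(c(5, 2, 1, 5))     # "H4"
classify_gametes <- function(pairs, presence_threshold = 1L) {
  m <- hap_count_matrix(pairs)
  k <- rowSums(m >= presence_threshold)
  if (any(k < 1))
    stop("classify_gametes: no haplotype reaches the presence threshold")
  paste0("H", k)
}

#' Four-gamete test summary across time points of interest
#'
#' Per time point, the percentage of linked pairs in each haplotype class
#' H1–H4 and the number of distinct biallelic sites involved; then the mean
#' across time points (`mode = "mean"`, the default) or a single pooled
#' percentage over all pairs (`mode = "pooled"`).
#'
#' @param pairs linkage data.frame (multiple samples allowed).
#' @param cfg an [run_config()] object (`presence_threshold`).
#' @param mode `"mean"` averages per-time-point percentages; `"pooled"`
#'   pools all pairs first.
#' @return list with `per_sample` (data.frame of percentages per sample) and
#'   `summary` (one-row data.frame: `H1,H2,H3,H4` percentages and
#'   `mean_biallelic_sites`).
#' @export
gamete_frequencies <- function(pairs, cfg = run_config(),
                               mode = c("mean", "pooled")) {
  mode <- match.arg(mode)
  if (!nrow(pairs)) {
    warning("gamete_frequencies: no classifiable pairs")
    return(list(per_sample = NULL, summary = NULL))
  }
  cls <- classify_gametes(pairs, cfg$presence_threshold)
  per <- lapply(split(seq_len(nrow(pairs)), pairs$sample), function(idx) {
    tab <- table(factor(cls[idx], levels = paste0("H", 1:4)))
    pc <- 100 * as.numeric(tab) / length(idx)
    sites <- unique(c(paste(pairs$contig[idx], pairs$pos_a[idx]),
                      paste(pairs$contig[idx], pairs$pos_b[idx])))
    data.frame(sample = pairs$sample[idx][1],
               H1 = pc[1], H2 = pc[2], H3 = pc[3], H4 = pc[4],
               n_pairs = length(idx), n_biallelic_sites = length(sites))
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  if (mode == "mean") {
    summ <- data.frame(H1 = mean(per$H1), H2 = mean(per$H2),
                       H3 = mean(per$H3), H4 = mean(per$H4),
                       mean_biallelic_sites = mean(per$n_biallelic_sites))
  } else {
    tab <- table(factor(cls, levels = paste0("H", 1:4)))
    pc <- 100 * as.numeric(tab) / length(cls)
    summ <- data.frame(H1 = pc[1], H2 = pc[2], H3 = pc[3], H4 = pc[4],
                       mean_biallelic_sites = mean(per$n_biallelic_sites))
  }
  list(per_sample = per, summary = summ)
}

#' Synonymous/nonsynonymous typing of an SNV site in codon context
#'
#' A site inside a gene is typed synonymous if substituting one allele for
#' the other at its codon position preserves the amino acid (background:
#' the contig consensus sequence), else nonsynonymous. Sites outside any
#' gene are `"noncoding"`. Minus-strand genes are handled by complementing
#' the alleles and reading the codon on the minus strand.
#'
#' @param contig contig identifiers (vectorized).
#' @param position 0-based positions.
#' @param allele1,allele2 the two alleles at the site (plus-strand bases).
#' @param genes gene-model data.frame.
#' @param sequences named character vector of contig sequences.
#' @return character vector: `"S"`, `"N"` or `"noncoding"`.
#' @export
site_mutation_type <- function(contig, position, allele1, allele2,
                               genes, sequences) {
  code <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(seq_along(position), function(i) {
    g <- genes[genes$contig == contig[i] &
                 genes$start <= position[i] & position[i] < genes$end, ,
               drop = FALSE]
    if (!nrow(g)) return("noncoding")
    g <- g[1, ]
    seq <- sequences[[g$contig]]
    if (g$strand == "+") {
      off <- position[i] - g$start
      cod_start <- g$start + (off %/% 3) * 3
      codon <- substr(seq, cod_start + 1, cod_start + 3)
      cp <- off %% 3 + 1
      a1 <- allele1[i]; a2 <- allele2[i]
    } else {
      off <- (g$end - 1) - position[i]
      cp <- off %% 3 + 1
      cod_end <- g$end - (off %/% 3) * 3        # 0-based exclusive
      fwd <- substr(seq, cod_end - 2, cod_end)
      codon <- paste(rev(comp[strsplit(fwd, "")[[1]]]), collapse = "")
      a1 <- comp[[allele1[i]]]; a2 <- comp[[allele2[i]]]
    }
    c1 <- codon; substr(c1, cp, cp) <- a1
    c2 <- codon; substr(c2, cp, cp) <- a2
    if (is.na(code[c1]) || is.na(code[c2])) return("N")
    if (code[[c1]] == code[[c2]]) "S" else "N"
  }, "")
}

# Pair-level mutation class from the two site types.
pair_mutation_class <- function(type_a, type_b) {
  ifelse(type_a == "noncoding" | type_b == "noncoding", "noncoding",
         ifelse(type_a == "S" & type_b == "S", "S-S",
                ifelse(type_a == "N" & type_b == "N", "N-N", "N-S")))
}

#' Linkage-decay curve binned by distance and mutation class
#'
#' Computes r2 for every classifiable pair, assigns each pair a mutation
#' class (S-S, N-S, N-N from codon context; pairs touching intergenic sites
#' are `noncoding`) and bins pair distances into closed `ld_bin`-wide ranges
#' aligned at 1 bp (1–10, 11–20, ...). Reports mean r2 and pair count per
#' bin and class; empty bins are omitted.
#'
#' @param pairs linkage data.frame.
#' @param genes gene-model data.frame.
#' @param sequences named character vector of contig sequences.
#' @param cfg an [run_config()] object.
#' @param include_noncoding keep the `noncoding` class in the output?
#' @return data.frame: `mutation_class, bin_start, bin_end, bin_label,
#'   mean_r2, n_pairs`.
#' @export
ld_decay_curve <- function(pairs, genes, sequences, cfg = run_config(),
                           include_noncoding = FALSE) {
  r2 <- pair_r2(pairs)
  keep <- !is.na(r2)
  pairs <- pairs[keep, , drop = FALSE]
  r2 <- r2[keep]
  if (!nrow(pairs))
    return(data.frame(mutation_class = character(), bin_start = integer(),
                      bin_end = integer(), bin_label = character(),
                      mean_r2 = numeric(), n_pairs = integer()))
  ta <- site_mutation_type(pairs$contig, pairs$pos_a,
                           pairs$allele_A, pairs$allele_a, genes, sequences)
  tb <- site_mutation_type(pairs$contig, pairs$pos_b,
                           pairs$allele_B, pairs$allele_b, genes, sequences)
  cls <- pair_mutation_class(ta, tb)
  d <- abs(pairs$pos_b - pairs$pos_a)
  bin <- (d - 1L) %/% cfg$ld_bin
  df <- data.frame(mutation_class = cls, bin = bin, r2 = r2)
  if (!include_noncoding)
    df <- df[df$mutation_class != "noncoding", , drop = FALSE]
  if (!nrow(df))
    return(data.frame(mutation_class = character(), bin_start = integer(),
                      bin_end = integer(), bin_label = character(),
                      mean_r2 = numeric(), n_pairs = integer()))
  agg <- do.call(rbind, lapply(
    split(df, list(df$mutation_class, df$bin), drop = TRUE),
    function(g) data.frame(mutation_class = g$mutation_class[1],
                           bin = g$bin[1],
                           mean_r2 = mean(g$r2),
                           n_pairs = nrow(g))))
  agg <- agg[order(agg$mutation_class, agg$bin), ]
  agg$bin_start <- agg$bin * cfg$ld_bin + 1L
  agg$bin_end <- (agg$bin + 1L) * cfg$ld_bin
  agg$bin_label <- sprintf("%d-%d", agg$bin_start, agg$bin_end)
  rownames(agg) <- NULL
  agg[, c("mutation_class", "bin_start", "bin_end", "bin_label",
          "mean_r2", "n_pairs")]
}
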