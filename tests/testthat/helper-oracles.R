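# Independent oracles, written against the stated definitions (not the
# package implementations) so that each check is a genuine dual route.

# --- SNV filter, applied literally per site -------------------------------
oracle_is_snv <- function(counts, min_coverage = 20, min_departure = 0.10) {
  counts <- as.numeric(counts)
  n <- sum(counts)
  if (n == 0) return(FALSE)
  p <- counts / n
  ent <- -sum(ifelse(p > 0, p * log2(p), 0))
  maf <- max(counts) / n
  ent > 0 && n >= min_coverage && (1 - maf) >= min_departure
}

# --- per-site pi by literal enumeration of read pairs ---------------------
oracle_site_pi <- function(counts) {
  reads <- rep(c("A", "C", "G", "T"), times = as.integer(counts))
  n <- length(reads)
  if (n < 2) return(NA_real_)
  mism <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (reads[i] != reads[j]) mism <- mism + 1L
  mism / choose(n, 2)
}

# --- r2 directly from the two-locus frequency formula ---------------------
oracle_r2 <- function(AB, Ab, aB, ab) {
  n <- AB + Ab + aB + ab
  fA <- (AB + Ab) / n
  fB <- (AB + aB) / n
  if (fA %in% c(0, 1) || fB %in% c(0, 1)) return(NA_real_)
  D <- AB / n - fA * fB
  D^2 / (fA * (1 - fA) * fB * (1 - fB))
}

# --- Hudson per-site components, written out longhand ---------------------
oracle_hudson <- function(p1, n1, p2, n2) {
  num <- (p1 - p2) * (p1 - p2) -
    p1 * (1 - p1) / (n1 - 1) -
    p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  c(num = num, den = den)
}

# --- Nei-Gojobori 1986, pathway enumeration -------------------------------
# Independent implementation: recursion over mutation orderings, explicit
# 9-change site counting per codon. Convention (matches package docs):
# stop-codon changes excluded from potential-site fractions, stop-passing
# pathways excluded from difference averaging with all-path fallback.
oracle_ng86 <- function(s1, s2) {
  gc <- Biostrings::GENETIC_CODE
  codons1 <- regmatches(s1, gregexpr("...", s1))[[1]]
  codons2 <- regmatches(s2, gregexpr("...", s2))[[1]]

  syn_sites <- function(codon) {
    total <- 0
    for (p in 1:3) {
      nsyn <- 0; nvalid <- 0
      for (alt in c("A", "C", "G", "T")) {
        if (alt == substr(codon, p, p)) next
        mut <- paste0(substr(codon, 1, p - 1), alt, substr(codon, p + 1, 3))
        if (gc[[mut]] == "*") next
        nvalid <- nvalid + 1
        if (gc[[mut]] == gc[[codon]]) nsyn <- nsyn + 1
      }
      if (nvalid > 0) total <- total + nsyn / nvalid
    }
    total
  }

  walk_paths <- function(from, to, allow_stop) {
    diffs <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(diffs)) return(list(c(0, 0)))
    out <- list()
    for (p in diffs) {
      mid <- paste0(substr(from, 1, p - 1), substr(to, p, p),
                    substr(from, p + 1, 3))
      if (!allow_stop && gc[[mid]] == "*") next
      step <- if (gc[[from]] == gc[[mid]]) c(1, 0) else c(0, 1)
      for (rest in walk_paths(mid, to, allow_stop))
        out[[length(out) + 1]] <- step + rest
    }
    out
  }

  S <- (sum(sapply(codons1, syn_sites)) + sum(sapply(codons2, syn_sites))) / 2
  N <- 3 * length(codons1) - S
  Sd <- 0; Nd <- 0
  for (i in seq_along(codons1)) {
    paths <- walk_paths(codons1[i], codons2[i], allow_stop = FALSE)
    if (!length(paths)) paths <- walk_paths(codons1[i], codons2[i], TRUE)
    avg <- Reduce(`+`, paths) / length(paths)
    Sd <- Sd + avg[1]; Nd <- Nd + avg[2]
  }
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  c(dN = jc(pN), dS = jc(pS), pN = pN, pS = pS, N = N, S = S,
    Nd = Nd, Sd = Sd)
}

# --- random fixtures ------------------------------------------------------
random_allele_counts <- function(n, samples = c("TP1", "TP2"),
                                 max_count = 200) {
  data.frame(contig = sample(c("c1", "c2"), n, replace = TRUE),
             position = sample.int(10 * n, n),
             sample = sample(samples, n, replace = TRUE),
             ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
             A = rpois(n, runif(n, 0, max_count / 4)),
             C = rpois(n, runif(n, 0, max_count / 4)),
             G = rpois(n, runif(n, 0, max_count / 4)),
             T = rpois(n, runif(n, 0, max_count / 4)))
}

random_linkage <- function(n) {
  base <- c("A", "C", "G", "T")
  al <- t(replicate(n, sample(base, 2)))
  bl <- t(replicate(n, sample(base, 2)))
  data.frame(contig = "c1",
             pos_a = sample.int(5000, n),
             pos_b = sample.int(5000, n) + 5000L,
             sample = sample(c("TP1", "TP2"), n, replace = TRUE),
             allele_A = al[, 1], allele_a = al[, 2],
             allele_B = bl[, 1], allele_b = bl[, 2],
             n_AB = rpois(n, 20) + 1L, n_Ab = rpois(n, 5),
             n_aB = rpois(n, 5), n_ab = rpois(n, 20))
}

random_codon_seq <- function(n_codons) {
  sense <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                     c("A","C","G","T")), 1,
                         paste, collapse = ""),
                   c("TAA", "TAG", "TGA"))
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# mutate a codon sequence at ~rate per base, avoiding stop codons
mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  gc <- Biostrings::GENETIC_CODE
  for (i in seq_along(chars)) {
    if (runif(1) >= rate) next
    old <- chars[i]
    for (alt in sample(setdiff(c("A","C","G","T"), old))) {
      chars[i] <- alt
      cod_start <- ((i - 1) %/% 3) * 3 + 1
      codon <- paste(chars[cod_start:(cod_start + 2)], collapse = "")
      if (gc[[codon]] != "*") break
      chars[i] <- old
    }
  }
  paste(chars, collapse = "")
}
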