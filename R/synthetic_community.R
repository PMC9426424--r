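# Ground-truthed synthetic strain-mixture communities. The generator stands
# in for a real metagenomic time series: it emits exactly the tables the
# pipeline consumes (allele counts, linkage, gene coverage, GFF3, FASTA)
# from a known strain mixture, so every downstream statistic has a
# recoverable truth. It is a stand-in, not a model of the sampled habitat:
# sites are independent Poisson-covered, strains follow a star genealogy
# (each SNV arises in exactly one strain; no back-mutation), and
# recombination is per-pair allele re-assortment.

#' Simulation configuration
#'
#' @param genome_length contig length in bp.
#' @param n_genes number of protein-coding genes laid on the contig.
#' @param coverage mean read coverage (Poisson lambda) at single-copy loci.
#' @param fragment_length read-pair fragment span in bp; only site pairs
#'   closer than this are observable as linked pairs.
#' @param error_rate per-base sequencing error rate, in \[0, 0.01\].
#' @param seed integer random seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 50000L, n_genes = 40L,
                       coverage = 100, fragment_length = 300L,
                       error_rate = 0, seed = 1L) {
  if (coverage <= 0) stop("sim_config: coverage must be > 0")
  if (error_rate < 0 || error_rate > 0.01)
    stop("sim_config: error_rate must be in [0, 0.01]")
  structure(list(genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes),
                 coverage = coverage,
                 fragment_length = as.integer(fragment_length),
                 error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Community (truth) specification
#'
#' @param fractions time-point-by-strain matrix of strain fractions; each
#'   row must lie on the simplex (sum 1). Row names are sample identifiers
#'   (defaults `TP1..`), column count gives the number of strains (1–8).
#' @param snv_density strain-discriminating SNV sites per kbp.
#' @param recomb_rate re-assortment probability for a 100-bp-separated site
#'   pair per transmitted fragment (see [simulate_linked_pairs()]); 0
#'   disables recombination.
#' @param gene_copy optional strain-by-gene copy-number matrix (1 = single
#'   chromosomal copy, 0 = absent, k > 1 = multi-copy element); defaults to
#'   all-1. Columns named `gene<N>` or positional.
#' @param swept_genes gene ids forced monomorphic across strains (no
#'   discriminating site falls inside them).
#' @return list of class `community_spec`.
#' @export
community_spec <- function(fractions, snv_density = 20,
                           recomb_rate = 0, gene_copy = NULL,
                           swept_genes = character()) {
  fractions <- as.matrix(fractions)
  n_strains <- ncol(fractions)
  if (n_strains < 1 || n_strains > 8)
    stop("community_spec: 1-8 strains supported")
  if (any(abs(rowSums(fractions) - 1) > 1e-9))
    stop("community_spec: fraction rows must sum to 1")
  if (any(fractions < 0))
    stop("community_spec: negative strain fraction")
  if (is.null(rownames(fractions)))
    rownames(fractions) <- paste0("TP", seq_len(nrow(fractions)))
  structure(list(n_strains = n_strains, fractions = fractions,
                 snv_density = snv_density, recomb_rate = recomb_rate,
                 gene_copy = gene_copy, swept_genes = swept_genes),
            class = "community_spec")
}

SENSE_CODONS <- setdiff(
  apply(expand.grid(NUCS, NUCS, NUCS), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

# Lay n_genes ORFs (ATG + sense codons + TAA) on a random contig; every
# fourth gene is minus-strand. Returns list(sequence, genes).
build_genome <- function(sim) {
  len <- sim$genome_length
  chars <- sample(NUCS, len, replace = TRUE)
  per_gene <- len %/% sim$n_genes
  gap <- 60L
  gene_len <- ((per_gene - gap) %/% 3) * 3
  if (gene_len < 90) stop("build_genome: genome too short for n_genes")
  genes <- data.frame(gene_id = sprintf("gene%03d", seq_len(sim$n_genes)),
                      contig = "contig1",
                      start = (seq_len(sim$n_genes) - 1L) * per_gene,
                      end = (seq_len(sim$n_genes) - 1L) * per_gene + gene_len,
                      strand = ifelse(seq_len(sim$n_genes) %% 4 == 0,
                                      "-", "+"),
                      contig_length = len)
  for (i in seq_len(nrow(genes))) {
    ncod <- gene_len / 3 - 2
    orf <- paste0("ATG",
                  paste(sample(SENSE_CODONS, ncod, replace = TRUE),
                        collapse = ""),
                  "TAA")
    if (genes$strand[i] == "-") orf <- revcomp(orf)
    chars[(genes$start[i] + 1):(genes$end[i])] <- strsplit(orf, "")[[1]]
  }
  list(sequence = paste(chars, collapse = ""), genes = genes)
}

# Distance-dependent re-assortment probability: recomb_rate is calibrated at
# a 100-bp pair separation and compounds with distance, so linkage decays.
reassort_prob <- function(recomb_rate, distance) {
  1 - (1 - recomb_rate)^(distance / 100)
}

gene_of_position <- function(position, genes) {
  idx <- rep(NA_integer_, length(position))
  for (i in seq_len(nrow(genes))) {
    hit <- position >= genes$start[i] & position < genes$end[i]
    idx[hit] <- i
  }
  idx
}

#' Generate a synthetic strain-mixture community
#'
#' Builds a random genome with gene models, places strain-discriminating
#' biallelic SNV sites (star genealogy: each site's derived allele arises in
#' exactly one strain; swept genes receive none), and simulates, per time
#' point: per-site allele counts under Poisson coverage weighted by the
#' mixture copy number, read-pair linkage tables (see
#' [simulate_linked_pairs()]), and per-gene mean coverage. Deterministic
#' given `sim$seed`.
#'
#' @param spec a [community_spec()].
#' @param sim a [sim_config()].
#' @return list: `truth` (class `strain_truth`), `allele_counts`,
#'   `linkage`, `coverage` (data.frames), `genes` (gene models),
#'   `sequences` (named character vector).
#' @export
generate_community <- function(spec, sim = sim_config()) {
  stopifnot(inherits(spec, "community_spec"), inherits(sim, "sim_config"))
  set.seed(sim$seed)
  genome <- build_genome(sim)
  genes <- genome$genes
  unknown_swept <- setdiff(spec$swept_genes, genes$gene_id)
  if (length(unknown_swept))
    stop("generate_community: unknown swept gene ", unknown_swept[1])

  gene_copy <- spec$gene_copy
  if (is.null(gene_copy))
    gene_copy <- matrix(1, spec$n_strains, nrow(genes))
  if (is.null(colnames(gene_copy))) colnames(gene_copy) <- genes$gene_id
  stopifnot(nrow(gene_copy) == spec$n_strains,
            ncol(gene_copy) == nrow(genes))

  # discriminating sites: uniform over the contig, outside swept genes
  n_sites <- max(0L, round(spec$snv_density * sim$genome_length / 1000))
  swept <- genes[genes$gene_id %in% spec$swept_genes, , drop = FALSE]
  allowed <- rep(TRUE, sim$genome_length)
  for (i in seq_len(nrow(swept)))
    allowed[(swept$start[i] + 1):swept$end[i]] <- FALSE
  pool <- which(allowed) - 1L
  n_sites <- min(n_sites, length(pool))
  positions <- sort(sample(pool, n_sites))
  genome_chars <- strsplit(genome$sequence, "")[[1]]
  ref <- genome_chars[positions + 1L]
  derived <- vapply(ref, function(b) sample(setdiff(NUCS, b), 1), "")
  carrier <- sample.int(spec$n_strains, n_sites, replace = TRUE)
  hap <- matrix(0L, spec$n_strains, n_sites)
  hap[cbind(carrier, seq_len(n_sites))] <- 1L
  gene_idx <- gene_of_position(positions, genes)
  site_positions <- data.frame(contig = "contig1", position = positions,
                               ref = unname(ref), derived = unname(derived),
                               carrier = carrier,
                               gene_id = ifelse(is.na(gene_idx), NA,
                                                genes$gene_id[gene_idx]))

  truth <- structure(list(n_strains = spec$n_strains, haplotypes = hap,
                          site_positions = site_positions,
                          gene_copy = gene_copy,
                          fractions = spec$fractions,
                          recomb_rate = spec$recomb_rate,
                          swept_genes = spec$swept_genes),
                     class = "strain_truth")

  samples <- rownames(spec$fractions)
  eps <- sim$error_rate

  # per-site mixture weights (copy-number weighted) per sample
  copy_at_site <- matrix(1, spec$n_strains, n_sites)
  in_gene <- !is.na(gene_idx)
  copy_at_site[, in_gene] <- gene_copy[, gene_idx[in_gene], drop = FALSE]

  ac_rows <- vector("list", length(samples))
  cov_rows <- vector("list", length(samples))
  link_rows <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    f <- spec$fractions[si, ]
    w <- copy_at_site * f                       # strain x site
    W <- colSums(w)
    p_derived <- colSums(w * hap) / W
    n <- rpois(n_sites, sim$coverage * W)
    k <- rbinom(n_sites, n, p_derived)
    counts <- matrix(0L, n_sites, 4, dimnames = list(NULL, NUCS))
    ref_i <- match(ref, NUCS)
    der_i <- match(derived, NUCS)
    counts[cbind(seq_len(n_sites), ref_i)] <- n - k
    counts[cbind(seq_len(n_sites), der_i)] <-
      counts[cbind(seq_len(n_sites), der_i)] + k
    if (eps > 0) {
      for (j in seq_len(n_sites)) {
        for (b in which(counts[j, ] > 0)) {
          e <- rbinom(1, counts[j, b], eps)
          if (e > 0) {
            counts[j, b] <- counts[j, b] - e
            tgt <- sample(setdiff(1:4, b), e, replace = TRUE)
            for (t in tgt) counts[j, t] <- counts[j, t] + 1L
          }
        }
      }
    }
    ac_rows[[si]] <- data.frame(contig = "contig1", position = positions,
                                sample = samples[si], ref = unname(ref),
                                A = counts[, 1], C = counts[, 2],
                                G = counts[, 3], T = counts[, 4])
    g_w <- as.numeric(f %*% gene_copy)          # copies per genome per gene
    g_len <- genes$end - genes$start
    g_cov <- rpois(nrow(genes), sim$coverage * g_w * g_len) / g_len
    cov_rows[[si]] <- data.frame(gene_id = genes$gene_id,
                                 sample = samples[si],
                                 mean_coverage = g_cov)
    link_rows[[si]] <- simulate_linked_pairs(truth, sim, samples[si])
  }

  list(truth = truth,
       allele_counts = do.call(rbind, ac_rows),
       linkage = do.call(rbind, link_rows),
       coverage = do.call(rbind, cov_rows),
       genes = genes,
       sequences = c(contig1 = genome$sequence))
}

#' Simulate read-pair linkage tables from a strain truth
#'
#' For every pair of discriminating sites closer than the fragment length,
#' draws Poisson many spanning fragments, each from a strain sampled by the
#' time point's fractions. With probability
#' `1 - (1 - recomb_rate)^(d/100)` (d = pair distance, bp) the second
#' site's allele is re-assorted from an independently sampled strain,
#' creating the recombinant haplotypes the four-gamete test detects; with
#' `recomb_rate = 0` and no sequencing error only parental haplotypes can
#' occur (never four, under the star genealogy). Sequencing error flips an
#' observed allele to the site's other allele at the per-base error rate.
#'
#' @param truth a `strain_truth` (from [generate_community()]).
#' @param sim a [sim_config()].
#' @param sample time point identifier (row of `truth$fractions`).
#' @return linkage data.frame (see [read_linkage_table()]); haplotype `A`/
#'   `B` label the reference alleles. Pairs with zero spanning fragments
#'   are omitted.
#' @export
simulate_linked_pairs <- function(truth, sim, sample) {
  f <- truth$fractions[sample, ]
  sp <- truth$site_positions
  n_sites <- nrow(sp)
  if (n_sites < 2) return(empty_linkage())
  pos <- sp$position
  # candidate pairs within fragment length (sites are sorted)
  ii <- integer(); jj <- integer()
  j <- 1L
  for (i in seq_len(n_sites - 1L)) {
    j <- max(j, i + 1L)
    while (j <= n_sites && pos[j] - pos[i] < sim$fragment_length) j <- j + 1L
    if (j - 1L >= i + 1L) {
      ii <- c(ii, rep(i, j - 1L - i))
      jj <- c(jj, (i + 1L):(j - 1L))
    }
  }
  if (!length(ii)) return(empty_linkage())
  d <- pos[jj] - pos[ii]
  lambda <- sim$coverage / 2 * pmax(0, 1 - d / sim$fragment_length)
  n_frag <- rpois(length(ii), lambda)
  keep <- n_frag > 0
  ii <- ii[keep]; jj <- jj[keep]; d <- d[keep]; n_frag <- n_frag[keep]
  if (!length(ii)) return(empty_linkage())
  p_re <- reassort_prob(truth$recomb_rate, d)
  hap <- truth$haplotypes
  eps <- sim$error_rate
  rows <- vector("list", length(ii))
  for (q in seq_along(ii)) {
    n <- n_frag[q]
    s <- sample.int(truth$n_strains, n, replace = TRUE, prob = f)
    ha <- hap[cbind(s, rep(ii[q], n))]
    hb <- hap[cbind(s, rep(jj[q], n))]
    if (p_re[q] > 0) {
      re <- runif(n) < p_re[q]
      if (any(re)) {
        s2 <- sample.int(truth$n_strains, sum(re), replace = TRUE, prob = f)
        hb[re] <- hap[cbind(s2, rep(jj[q], sum(re)))]
      }
    }
    if (eps > 0) {
      ha <- ifelse(runif(n) < eps, 1L - ha, ha)
      hb <- ifelse(runif(n) < eps, 1L - hb, hb)
    }
    # A/B = reference alleles (haplotype state 0)
    rows[[q]] <- data.frame(
      contig = sp$contig[ii[q]], pos_a = pos[ii[q]], pos_b = pos[jj[q]],
      sample = sample,
      allele_A = sp$ref[ii[q]], allele_a = sp$derived[ii[q]],
      allele_B = sp$ref[jj[q]], allele_b = sp$derived[jj[q]],
      n_AB = sum(ha == 0 & hb == 0), n_Ab = sum(ha == 0 & hb == 1),
      n_aB = sum(ha == 1 & hb == 0), n_ab = sum(ha == 1 & hb == 1))
  }
  do.call(rbind, rows)
}

empty_linkage <- function() {
  data.frame(contig = character(), pos_a = integer(), pos_b = integer(),
             sample = character(), allele_A = character(),
             allele_a = character(), allele_B = character(),
             allele_b = character(), n_AB = integer(), n_Ab = integer(),
             n_aB = integer(), n_ab = integer())
}

#' Observed derived-allele frequencies at the truth's sites
#'
#' @param allele_counts allele-count data.frame from [generate_community()].
#' @param truth the matching `strain_truth`.
#' @param sample time point identifier.
#' @return numeric vector of derived-allele frequencies, aligned with
#'   `truth$site_positions`; `NA` at uncovered sites.
#' @export
derived_allele_frequencies <- function(allele_counts, truth, sample) {
  ac <- allele_counts[allele_counts$sample == sample, , drop = FALSE]
  key <- paste(ac$contig, ac$position)
  idx <- match(paste(truth$site_positions$contig,
                     truth$site_positions$position), key)
  m <- count_matrix(ac)
  colnames(m) <- NUCS
  cov <- rowSums(m)
  out <- rep(NA_real_, nrow(truth$site_positions))
  for (i in seq_len(nrow(truth$site_positions))) {
    r <- idx[i]
    if (is.na(r) || cov[r] == 0) next
    out[i] <- m[r, truth$site_positions$derived[i]] / cov[r]
  }
  out
}

#' Estimate strain fractions from observed allele frequencies
#'
#' Solves the simplex-constrained least-squares problem
#' `min || H' w - f ||^2` subject to `w >= 0`, `sum(w) = 1`, where `H` is
#' the strain-by-site 0/1 haplotype matrix and `f` the observed
#' derived-allele frequencies. Solved exactly by enumerating active sets
#' (strain count is at most 8). Strains with identical haplotypes cannot be
#' separated: they are merged with a warning and the merged weight split
#' equally among them (see attribute `merged_groups`).
#'
#' @param freqs observed derived-allele frequencies (sites with `NA`
#'   dropped).
#' @param haplotypes strain-by-site 0/1 matrix.
#' @return numeric vector of strain fractions (sums to 1), with attribute
#'   `merged_groups` listing any indistinguishable strain groups.
#' @export
estimate_strain_fractions <- function(freqs, haplotypes) {
  H <- as.matrix(haplotypes)
  if (length(freqs) != ncol(H))
    stop("estimate_strain_fractions: freqs must have one value per site")
  ok <- !is.na(freqs)
  f <- freqs[ok]
  A_full <- t(H[, ok, drop = FALSE])            # sites x strains
  key <- apply(A_full, 2, paste, collapse = "")
  groups <- split(seq_len(ncol(A_full)), match(key, unique(key)))
  merged <- Filter(function(g) length(g) > 1, groups)
  if (length(merged))
    warning("estimate_strain_fractions: indistinguishable strains merged: ",
            paste(vapply(merged, paste, "", collapse = "+"), collapse = ", "))
  A <- A_full[, vapply(groups, `[`, 0L, 1L), drop = FALSE]
  K <- ncol(A)
  if (nrow(A) < K - 1)
    stop("estimate_strain_fractions: need at least n_strains - 1 sites")

  best <- NULL; best_obj <- Inf
  for (mask in seq_len(2^K) - 1L) {
    free <- which(bitwAnd(mask, 2^(seq_len(K) - 1L)) > 0)
    if (!length(free)) next
    Af <- A[, free, drop = FALSE]
    G <- crossprod(Af)
    kkt <- rbind(cbind(2 * G, 1), c(rep(1, length(free)), 0))
    rhs <- c(2 * crossprod(Af, f), 1)
    sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    wf <- sol[seq_along(free)]
    if (any(wf < -1e-9)) next
    w <- numeric(K); w[free] <- pmax(wf, 0)
    w <- w / sum(w)
    obj <- sum((A %*% w - f)^2)
    if (obj < best_obj - 1e-12) { best_obj <- obj; best <- w }
  }
  out <- numeric(nrow(H))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    out[g] <- best[gi] / length(g)
  }
  attr(out, "merged_groups") <- merged
  out
}

#' Write / read a strain truth as JSON text
#'
#' @param truth a `strain_truth`.
#' @param path file path.
#' @return `read_strain_truth()` returns a `strain_truth`.
#' @export
write_strain_truth <- function(truth, path) {
  x <- unclass(truth)
  x$haplotypes <- unname(apply(truth$haplotypes, 1, paste, collapse = ""))
  x$gene_copy_cols <- colnames(truth$gene_copy)
  x$gene_copy <- unname(asplit(truth$gene_copy, 1))
  x$fractions_rows <- rownames(truth$fractions)
  x$fractions <- unname(asplit(truth$fractions, 1))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_strain_truth
#' @export
read_strain_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  hap <- do.call(rbind, lapply(strsplit(x$haplotypes, ""), as.integer))
  as_mat <- function(v) if (is.list(v)) do.call(rbind, v) else as.matrix(v)
  gene_copy <- as_mat(x$gene_copy)
  colnames(gene_copy) <- x$gene_copy_cols
  fractions <- as_mat(x$fractions)
  rownames(fractions) <- x$fractions_rows
  structure(list(n_strains = x$n_strains, haplotypes = hap,
                 site_positions = as.data.frame(x$site_positions),
                 gene_copy = gene_copy, fractions = fractions,
                 recomb_rate = x$recomb_rate,
                 swept_genes = as.character(x$swept_genes)),
            class = "strain_truth")
}
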