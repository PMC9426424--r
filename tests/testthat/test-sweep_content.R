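test_that("Welch p-values match stats::t.test where both are defined", {
  set.seed(51)
  for (i in 1:50) {
    x <- rnorm(20, 0, 1)
    y <- rnorm(300, 0.2, 1.5)
    want <- stats::t.test(x, y, alternative = "less")$p.value
    expect_equal(aquiferpop:::welch_p(x, y, "less"), want, tolerance = 1e-12)
    want2 <- stats::t.test(x, y)$p.value
    expect_equal(aquiferpop:::welch_p(x, y, "two.sided"), want2,
                 tolerance = 1e-12)
  }
  # degenerate inputs are deterministic instead of erroring
  expect_equal(aquiferpop:::welch_p(rep(0, 5), rep(0, 9)), 1)
  expect_equal(aquiferpop:::welch_p(rep(0, 5), rep(1, 9)), 0)
  expect_equal(aquiferpop:::welch_p(rep(1, 5), rep(0, 9)), 1)
})

make_pi_lists <- function(gene_sites, genome_sites, tps = c("TP1", "TP2")) {
  gene_pi <- lapply(tps, function(tp) gene_sites)
  names(gene_pi) <- tps
  genome_pi <- lapply(tps, function(tp) genome_sites)
  names(genome_pi) <- tps
  list(gene = gene_pi, genome = genome_pi)
}

test_that("low_diversity_genes flags swept genes and groups runs", {
  set.seed(52)
  genome_sites <- c(runif(300, 0, 0.05), numeric(700))
  genes <- paste0("g", 1:8)
  gene_sites <- setNames(rep(list(sample(genome_sites, 100)), 8), genes)
  gene_sites[["g3"]] <- numeric(100)  # swept: zero diversity
  gene_sites[["g4"]] <- numeric(100)
  gene_sites[["g5"]] <- numeric(100)
  gene_sites[["g8"]] <- numeric(5)    # too few sites -> untested
  pl <- make_pi_lists(NULL, genome_sites)
  gene_pi <- lapply(pl$genome, function(x) gene_sites)
  calls <- low_diversity_genes(gene_pi, pl$genome, genes)
  expect_true(all(calls$flagged[calls$gene_id %in% c("g3", "g4", "g5")]))
  expect_false(any(calls$flagged[calls$gene_id %in% c("g1", "g2", "g6")]))
  expect_false(calls$tested[calls$gene_id == "g8"])
  expect_equal(unique(calls$run_length[calls$flagged]), 3L)
  expect_equal(unique(calls$run_id[calls$flagged]), 1L)
})

test_that("a gene drawn from the genome distribution is not flagged", {
  set.seed(53)
  genome_sites <- c(runif(200, 0, 0.05), numeric(800))
  gene_pi <- list(TP1 = list(g1 = genome_sites))
  genome_pi <- list(TP1 = genome_sites)
  calls <- low_diversity_genes(gene_pi, genome_pi, "g1")
  expect_false(calls$flagged[1])
})

test_that("Hudson per-site components match the formula", {
  x <- hudson_fst_site(1, 100, 0, 100)
  expect_equal(x$numerator / x$denominator, 1)
  x <- hudson_fst_site(0.5, 11, 0.5, 11)
  expect_equal(x$numerator, -0.05)
  expect_equal(x$denominator, 0.5)
  expect_equal(x$numerator / x$denominator, -0.1)
  x <- hudson_fst_site(0.9, 10, 0.1, 10)
  expect_equal(x$numerator, 0.62)
  expect_equal(x$denominator, 0.82)
  expect_equal(x$numerator / x$denominator, 0.62 / 0.82)

  set.seed(54)
  for (i in 1:100) {
    p1 <- runif(1); p2 <- runif(1)
    n1 <- sample(2:200, 1); n2 <- sample(2:200, 1)
    got <- hudson_fst_site(p1, n1, p2, n2)
    want <- oracle_hudson(p1, n1, p2, n2)
    expect_equal(got$numerator, unname(want["num"]), tolerance = 1e-12)
    expect_equal(got$denominator, unname(want["den"]), tolerance = 1e-12)
  }
  expect_error(hudson_fst_site(0.5, 1, 0.5, 10))
})

test_that("per-gene F_ST is a ratio of sums over usable sites", {
  genes <- data.frame(gene_id = c("g1", "g2"), contig = "c1",
                      start = c(0L, 100L), end = c(100L, 200L),
                      strand = "+", contig_length = 200L)
  freqs <- data.frame(contig = "c1", position = c(10L, 20L, 150L, 160L),
                      p1 = c(0.9, 0.8, 0.5, 0), n1 = 50,
                      p2 = c(0.1, 0.2, 0.5, 0), n2 = 50)
  gf <- fst_by_gene(freqs, genes)
  comp <- oracle_hudson(0.9, 50, 0.1, 50) + oracle_hudson(0.8, 50, 0.2, 50)
  expect_equal(gf$fst[gf$gene_id == "g1"],
               unname(comp["num"] / comp["den"]))
  # g2: one negative-numerator site plus one zero-denominator site (skipped)
  expect_equal(gf$n_sites[gf$gene_id == "g2"], 1L)
  expect_lt(gf$fst[gf$gene_id == "g2"], 0)
})

test_that("window scan finds injected blocks and is threshold-monotone", {
  set.seed(55)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:40), contig = "c1",
                      start = (0:39) * 100L, end = (0:39) * 100L + 90L,
                      strand = "+", contig_length = 4000L)
  base <- data.frame(gene_id = genes$gene_id,
                     fst = rnorm(40, 0, 0.02))
  scan0 <- window_fst_scan(base, genes)
  expect_equal(sum(scan0$windows$elevated_1sd),
               sum(scan0$windows$mean_fst >
                     scan0$genome_mean + scan0$genome_sd))
  injected <- base
  injected$fst[18:22] <- 0.8  # five-gene differentiated block
  scan1 <- window_fst_scan(injected, genes)
  expect_gte(scan1$regions["sd1"], 1)
  expect_lte(scan1$regions["sd2"], scan1$regions["sd1"])

  # uniform F_ST: zero elevated regions at any level
  flat <- data.frame(gene_id = genes$gene_id, fst = 0.1)
  scanf <- window_fst_scan(flat, genes)
  expect_equal(unname(scanf$regions), c(0L, 0L))

  # contig with fewer genes than the window yields no windows
  few <- base[1:3, ]
  scan_few <- window_fst_scan(few, genes[1:3, ])
  expect_null(scan_few$windows)
})

test_that("F_ST eligibility screens start/stop codons and coverage", {
  com <- generate_community(
    community_spec(rbind(TP1 = c(0.7, 0.3)), snv_density = 5),
    sim_config(genome_length = 10000, n_genes = 8, seed = 56))
  ids <- eligible_fst_genes(com$genes, com$sequences)
  expect_setequal(ids, com$genes$gene_id)  # generator emits complete ORFs
  cov <- com$coverage
  cov$mean_coverage[cov$gene_id == "gene001"] <- 1e6  # wild outlier
  ids2 <- eligible_fst_genes(com$genes, com$sequences, cov)
  expect_false("gene001" %in% ids2)
})

test_that("gene frequency divides by the sample median", {
  cov <- data.frame(gene_id = rep(paste0("g", 1:4), 2),
                    sample = rep(c("TP1", "TP2"), each = 4),
                    mean_coverage = c(10, 10, 10, 20, 10, 10, 10, 2))
  gf <- gene_frequency(cov)
  expect_equal(unname(gf$frequencies[, "TP1"]), c(1, 1, 1, 2))
  expect_equal(gf$variable_genes, "g4")  # range 2 - 0.2 = 1.8 >= 1

  # scale invariance: multiplying a sample's coverages leaves it unchanged
  cov2 <- cov
  cov2$mean_coverage[cov2$sample == "TP1"] <-
    cov2$mean_coverage[cov2$sample == "TP1"] * 7.3
  expect_equal(gene_frequency(cov2)$frequencies, gf$frequencies)

  cov$mean_coverage[cov$sample == "TP2"] <- 0
  expect_error(gene_frequency(cov), "zero median")
})

test_that("short contigs are excluded from gene frequency", {
  cov <- data.frame(gene_id = c("g1", "g2"), sample = "TP1",
                    mean_coverage = c(10, 30))
  genes <- data.frame(gene_id = c("g1", "g2"), contig = c("c1", "c2"),
                      start = 0L, end = 900L, strand = "+",
                      contig_length = c(3000L, 1000L))
  gf <- gene_frequency(cov, genes)
  expect_equal(rownames(gf$frequencies), "g1")
})

test_that("sweep report reproduces printed percentage arithmetic", {
  counts <- norp_sweep_counts()
  # the two most extreme published rows, via the same half-up rule
  expect_equal(aquiferpop:::percent_half_up(190, 2182), 9L)
  expect_equal(aquiferpop:::percent_half_up(22, 3851), 1L)

  calls <- data.frame(gene_id = paste0("g", 1:5),
                      tested = TRUE,
                      flagged = c(TRUE, TRUE, FALSE, FALSE, TRUE),
                      run_id = c(1L, 1L, NA, NA, 2L),
                      run_length = c(2L, 2L, NA, NA, 1L))
  cats <- c(g1 = "below_genome_mean", g2 = "relaxed")
  rep <- summarize_sweep_report("m", 100, calls, cats,
                                c(sd1 = 3L, sd2 = 1L))
  expect_equal(rep$n_low_pi, 3L)
  expect_equal(rep$pct_low_pi, 3L)
  expect_equal(rep$n_no_dnds, 1L)          # g5 has no category
  expect_equal(rep$pct_low_dnds, 33L)
  expect_equal(rep$longest_low_pi_run, 2L)
  expect_equal(rep$fst_regions_1sd, 3L)

  none <- summarize_sweep_report("m", 100,
                                 transform(calls, flagged = FALSE), NULL)
  expect_equal(none$pct_low_dnds, 0L)
  expect_equal(none$pct_no_dnds, 0L)
  expect_equal(none$longest_low_pi_run, 0L)
})
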