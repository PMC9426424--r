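small_sim <- function(seed, ...) {
  sim_config(genome_length = 15000, n_genes = 12, coverage = 100,
             seed = seed, ...)
}

test_that("generation is deterministic given the seed", {
  spec <- community_spec(rbind(TP1 = c(0.7, 0.3), TP2 = c(0.4, 0.6)),
                         snv_density = 10, recomb_rate = 0.1)
  a <- generate_community(spec, small_sim(9))
  b <- generate_community(spec, small_sim(9))
  expect_identical(a$allele_counts, b$allele_counts)
  expect_identical(a$linkage, b$linkage)
  expect_identical(a$coverage, b$coverage)
  expect_identical(a$sequences, b$sequences)
  c <- generate_community(spec, small_sim(10))
  expect_false(identical(a$allele_counts, c$allele_counts))
})

test_that("a single error-free strain yields no SNVs", {
  com <- generate_community(
    community_spec(rbind(TP1 = 1), snv_density = 10),
    small_sim(12))
  expect_equal(nrow(call_snvs(com$allele_counts)), 0L)
})

test_that("mixture frequencies match the binomial expectation", {
  com <- generate_community(
    community_spec(rbind(TP1 = c(0.7, 0.3)), snv_density = 100 / 15),
    sim_config(genome_length = 15000, n_genes = 12, coverage = 200,
               seed = 13))
  snvs <- call_snvs(com$allele_counts)
  # ~100 sites at lambda 200: mean major-allele frequency ~ 0.7 within
  # 3 binomial standard errors of the site-level mean
  se <- sqrt(0.7 * 0.3 / 200) / sqrt(nrow(snvs))
  expect_lt(abs(mean(snvs$major_allele_frequency) - 0.7), 3 * se + 1e-3)
})

test_that("fraction specification is validated", {
  expect_error(community_spec(rbind(TP1 = c(0.7, 0.2))), "sum to 1")
  expect_error(community_spec(rbind(TP1 = c(1.2, -0.2))), "negative")
  expect_error(community_spec(matrix(1 / 9, 1, 9)), "1-8 strains")
  expect_error(generate_community(
    community_spec(rbind(TP1 = c(0.5, 0.5)), swept_genes = "nope"),
    small_sim(1)), "unknown swept gene")
})

test_that("swept genes harbour no discriminating sites at any coverage", {
  spec <- community_spec(rbind(TP1 = c(0.5, 0.5)), snv_density = 30,
                         swept_genes = c("gene002", "gene005"))
  com <- generate_community(spec, sim_config(genome_length = 15000,
                                             n_genes = 12, coverage = 400,
                                             seed = 14))
  expect_setequal(com$truth$swept_genes, c("gene002", "gene005"))
  expect_false(any(com$truth$site_positions$gene_id %in%
                     c("gene002", "gene005")))
  snvs <- call_snvs(com$allele_counts)
  g <- com$genes[com$genes$gene_id %in% c("gene002", "gene005"), ]
  for (i in seq_len(nrow(g)))
    expect_false(any(snvs$position >= g$start[i] & snvs$position < g$end[i]))
})

test_that("linkage respects the fragment length and parental haplotypes", {
  spec <- community_spec(rbind(TP1 = c(0.6, 0.4)), snv_density = 10)
  com <- generate_community(spec, small_sim(15))
  d <- abs(com$linkage$pos_b - com$linkage$pos_a)
  expect_true(all(d > 0 & d < 300))
  expect_false(any(classify_gametes(com$linkage) == "H4"))

  # fragment shorter than the closest site spacing -> no observable pairs
  sp <- com$truth$site_positions
  min_gap <- min(diff(sort(sp$position)))
  com2 <- generate_community(spec, small_sim(15, fragment_length = min_gap))
  expect_equal(nrow(com2$truth$site_positions), nrow(sp))
  expect_equal(nrow(simulate_linked_pairs(
    com2$truth, small_sim(15, fragment_length = 1), "TP1")), 0L)
})

test_that("recombinant haplotypes appear once re-assortment is enabled", {
  spec <- community_spec(rbind(TP1 = c(0.5, 0.5)), snv_density = 10,
                         recomb_rate = 0.5)
  com <- generate_community(spec, sim_config(genome_length = 15000,
                                             n_genes = 12, coverage = 300,
                                             seed = 16))
  gf <- gamete_frequencies(com$linkage)
  expect_gt(gf$summary$H4, 0)
})

test_that("strain fractions are recovered exactly from noiseless input", {
  # two complementary strains observed at 0.7 on every strain-1 allele
  H <- rbind(rep(1, 40), rep(0, 40))
  w <- estimate_strain_fractions(rep(0.7, 40), H)
  expect_equal(as.numeric(w), c(0.7, 0.3), tolerance = 1e-9)

  # three strains, noiseless mixture of random haplotypes
  set.seed(17)
  H3 <- matrix(rbinom(3 * 60, 1, 0.5), 3, 60)
  truth_w <- c(0.5, 0.3, 0.2)
  f <- as.numeric(truth_w %*% H3)
  w3 <- estimate_strain_fractions(f, H3)
  expect_equal(as.numeric(w3), truth_w, tolerance = 1e-6)

  # duplicate strains are merged with a warning
  Hd <- rbind(H3[1, ], H3[1, ], H3[3, ])
  expect_warning(wd <- estimate_strain_fractions(f, Hd), "merged")
  expect_equal(length(attr(wd, "merged_groups")), 1L)
  expect_equal(sum(wd), 1, tolerance = 1e-9)

  # 4 distinguishable strains but only 2 sites: underdetermined
  H4 <- rbind(c(1, 0), c(0, 1), c(1, 1), c(0, 0))
  expect_error(estimate_strain_fractions(c(0.5, 0.5), H4), "at least")
  expect_error(estimate_strain_fractions(c(0.5), H4), "per site")
})

test_that("truth objects roundtrip through the JSON text format", {
  spec <- community_spec(rbind(TP1 = c(0.7, 0.3), TP2 = c(0.2, 0.8)),
                         snv_density = 5, recomb_rate = 0.2,
                         swept_genes = "gene001")
  com <- generate_community(spec, small_sim(18))
  tf <- withr::local_tempfile(fileext = ".json")
  write_strain_truth(com$truth, tf)
  back <- read_strain_truth(tf)
  expect_equal(back$haplotypes, com$truth$haplotypes, ignore_attr = TRUE)
  expect_equal(back$fractions, com$truth$fractions)
  expect_equal(back$site_positions$position,
               com$truth$site_positions$position)
  expect_equal(back$recomb_rate, 0.2)
  expect_equal(back$swept_genes, "gene001")
})

test_that("gene copy numbers drive coverage as mixture-weighted copies", {
  gene_copy <- matrix(1, 2, 12)
  gene_copy[2, 7] <- 4  # strain 2 carries a 4-copy element at gene007
  spec <- community_spec(rbind(TP1 = c(0.9, 0.1), TP2 = c(0.1, 0.9)),
                         snv_density = 5, gene_copy = gene_copy)
  com <- generate_community(spec, small_sim(19))
  gf <- gene_frequency(com$coverage, com$genes)
  traj <- gf$frequencies["gene007", ]
  expect_equal(unname(traj["TP1"]), 0.9 * 1 + 0.1 * 4, tolerance = 0.1)
  expect_equal(unname(traj["TP2"]), 0.1 * 1 + 0.9 * 4, tolerance = 0.35)
  expect_true("gene007" %in% gf$variable_genes)
})
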