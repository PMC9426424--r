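test_that("pair_r2 matches the two-locus frequency formula", {
  expect_equal(pair_r2(c(50, 0, 0, 50)), 1)
  expect_equal(pair_r2(c(25, 25, 25, 25)), 0)
  expect_equal(pair_r2(c(40, 10, 10, 40)), 0.36)
  expect_true(is.na(pair_r2(c(10, 5, 0, 0))))   # site b monomorphic
  expect_error(pair_r2(c(0, 0, 0, 0)), "empty")

  set.seed(31)
  for (i in 1:200) {
    cnt <- rpois(4, runif(4, 0, 15))
    if (sum(cnt) < 1) next
    got <- pair_r2(cnt)
    want <- oracle_r2(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(got, want, tolerance = 1e-12)
    if (!is.na(got)) expect_true(got >= 0 && got <= 1 + 1e-12)
  }
})

test_that("r2 is 1 exactly for two complementary haplotypes", {
  set.seed(32)
  for (i in 1:20) {
    ab <- sample.int(50, 2)
    expect_equal(pair_r2(c(ab[1], 0, 0, ab[2])), 1)
    expect_equal(pair_r2(c(0, ab[1], ab[2], 0)), 1)
  }
})

test_that("four-gamete classification counts present haplotypes", {
  expect_equal(classify_gametes(c(5, 0, 0, 5)), "H2")
  expect_equal(classify_gametes(c(5, 2, 1, 5)), "H4")
  expect_equal(classify_gametes(c(10, 0, 0, 0)), "H1")
  expect_equal(classify_gametes(c(5, 0, 1, 5), presence_threshold = 2), "H2")
})

test_that("gamete_frequencies averages per time point and sums to 100", {
  pairs <- data.frame(contig = "c1",
                      pos_a = c(1L, 3L, 5L, 7L), pos_b = c(2L, 4L, 6L, 8L),
                      sample = "TP1",
                      allele_A = "A", allele_a = "C",
                      allele_B = "A", allele_b = "C",
                      n_AB = c(5L, 5L, 5L, 5L), n_Ab = c(0L, 0L, 2L, 2L),
                      n_aB = c(0L, 0L, 0L, 1L), n_ab = c(5L, 5L, 5L, 5L))
  gf <- gamete_frequencies(pairs)
  expect_equal(gf$summary$H2, 50)
  expect_equal(gf$summary$H3, 25)
  expect_equal(gf$summary$H4, 25)
  expect_equal(gf$summary$mean_biallelic_sites, 8)
  expect_equal(rowSums(gf$per_sample[, c("H1", "H2", "H3", "H4")]),
               100, ignore_attr = TRUE, tolerance = 0.01)

  # mean vs pooled modes differ when samples are unbalanced
  pairs2 <- rbind(pairs, transform(pairs[1, ], sample = "TP2"))
  gf2 <- gamete_frequencies(pairs2, mode = "mean")
  expect_equal(gf2$summary$H2, mean(c(50, 100)))
  gfp <- gamete_frequencies(pairs2, mode = "pooled")
  expect_equal(gfp$summary$H2, 100 * 3 / 5)
  expect_warning(gamete_frequencies(pairs[0, ]), "no classifiable")
})

test_that("mutation typing reads the codon context on both strands", {
  # gene1 on +: positions 0..8 spell ATG TTT AAA; third codon position of
  # TTT is position 5; T->C gives TTC, still Phe -> synonymous
  seqs <- c(c1 = "ATGTTTAAATTTTTTTTT")
  genes <- data.frame(gene_id = "g1", contig = "c1", start = 0L, end = 9L,
                      strand = "+", contig_length = 18L)
  expect_equal(site_mutation_type("c1", 5L, "T", "C", genes, seqs), "S")
  # first codon position of TTT: T->C gives CTT (Leu) -> nonsynonymous
  expect_equal(site_mutation_type("c1", 3L, "T", "C", genes, seqs), "N")
  # outside any gene
  expect_equal(site_mutation_type("c1", 12L, "T", "C", genes, seqs),
               "noncoding")

  # minus-strand gene: contig holds revcomp(ATGTTTAAA) = TTTAAACAT at 0..8;
  # plus-strand position 1 is codon 2 position 3 on the minus strand
  seqs2 <- c(c1 = "TTTAAACATGGGGGGGGG")
  genes2 <- data.frame(gene_id = "g2", contig = "c1", start = 0L, end = 9L,
                       strand = "-", contig_length = 18L)
  # minus-strand codon TTT, third position; plus alleles A/G are minus T/C
  expect_equal(site_mutation_type("c1", 0L, "A", "G", genes2, seqs2), "S")
  # minus-strand codon AAA position 1 (plus position 5): T->C on minus
  # strand gives AAA->GAA? plus allele T<->C maps to minus A<->G: Lys->Glu
  expect_equal(site_mutation_type("c1", 5L, "T", "C", genes2, seqs2), "N")
})

test_that("decay curve bins distances into closed 10-bp ranges", {
  com <- generate_community(
    community_spec(rbind(TP1 = c(0.6, 0.4)), snv_density = 10),
    sim_config(genome_length = 15000, n_genes = 10, coverage = 100,
               seed = 41))
  d <- ld_decay_curve(com$linkage, com$genes, com$sequences)
  expect_true(all(d$bin_end - d$bin_start == 9L))
  expect_true(all(d$bin_start %% 10 == 1))
  expect_true(all(d$mutation_class %in% c("S-S", "N-S", "N-N")))
  expect_true(all(d$mean_r2 >= 0 & d$mean_r2 <= 1))

  # all pairs at distance 7 land in the single [1-10] bin
  pairs <- com$linkage[1, , drop = FALSE]
  pairs$pos_b <- pairs$pos_a + 7L
  d1 <- ld_decay_curve(pairs, com$genes, com$sequences,
                       include_noncoding = TRUE)
  expect_equal(nrow(d1), 1L)
  expect_equal(d1$bin_label, "1-10")
})

test_that("no-recombination no-error communities never show H4", {
  for (seed in 1:5) {
    com <- generate_community(
      community_spec(rbind(TP1 = c(0.5, 0.3, 0.2)), snv_density = 15,
                     recomb_rate = 0),
      sim_config(genome_length = 10000, n_genes = 8, coverage = 150,
                 seed = seed))
    if (!nrow(com$linkage)) next
    expect_false(any(classify_gametes(com$linkage) == "H4"))
  }
})
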