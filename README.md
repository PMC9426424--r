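# aquiferpop

Population genomics for metagenomic time series of microbial communities.

`aquiferpop` is for microbial ecologists who have mapped a metagenomic time
series against a set of metagenome-assembled genomes (MAGs) and want to ask
population-genetic questions of the read data: which populations are worth
analysing, how diverse each one is, whether its strains recombine, whether
individual genes show selective sweeps or differentiation, which genes vary
in copy number as strains come and go, and what selection acts on them. It
was built around the analysis style used for low-biomass subseafloor
aquifer communities, where populations are mixtures of a few strains whose
fractions shift between samplings.

Everything runs on plain text tables (per-site allele counts, read-linked
SNV pairs, per-gene coverages, GFF3 gene models, FASTA contigs), so any
mapper/profiler can feed it.

## The statistics at its core

* **Focal selection** — RPKM = reads / ((MAG kbp) × (sample Mbp));
  *persistent* populations have ≥ 5 RPKM in ≥ 3 samples, *spikes* reach
  ≥ 30 RPKM once.
* **SNV calling** — entropy > 0, coverage ≥ 20×, departure from consensus
  ≥ 10%; the consensus is the count-maximal allele, never the assembly
  reference.
* **Nucleotide diversity** — π per site is the unbiased two-read mismatch
  probability 1 − Σᵢ C(cᵢ,2)/C(n,2); gene/genome π averages covered sites
  (invariant sites count as 0).
* **Recombination** — r² = D²/(f_A(1−f_A)f_B(1−f_B)) from read-pair
  haplotype counts, binned into 10-bp distance ranges by mutation type
  (S-S, N-S, N-N); the four-gamete test reports the percentage of pairs
  showing 1–4 haplotypes (H4 implies recombination under infinite sites).
* **Sweep scan** — one-sided Welch t test of per-gene vs genome per-site π,
  BH-adjusted per time point, intersected across time points.
* **Differentiation** — Hudson F_ST per site, ratio-of-sums per gene,
  five-gene sliding windows called elevated beyond 1 or 2 SD of the genome
  mean and merged into regions.
* **Gene copy number** — gene coverage / sample median coverage = copies
  per genome; variable genes change by ≥ 1 copy across time points.
* **dN/dS** — Nei–Gojobori (1986) counting with Jukes–Cantor correction,
  pairs filtered to dN > 0, 0.01 < dS < 1, dN/dS < 5.

A ground-truthed synthetic strain-mixture generator
(`generate_community()`) emits every table above from a known world
(strain haplotypes, time-varying fractions, tunable re-assortment, imposed
sweeps, multi-copy elements, Poisson coverage), and
`estimate_strain_fractions()` recovers mixture fractions by
simplex-constrained least squares for truth-recovery testing.

## Worked example

```r
library(aquiferpop)

# a two-strain community sampled at two time points
fr <- rbind(TP1 = c(0.8, 0.2), TP2 = c(0.3, 0.7))
com <- generate_community(community_spec(fr, snv_density = 10),
                          sim_config(seed = 1))

diversity_summary(com$allele_counts, 50000)
#>   sample snv_count snv_density mean_major_allele_frequency genome_pi
#> 1    TP1       499        9.98                   0.7959139 0.3247227
#> 2    TP2       500       10.00                   0.7020952 0.4183753

gamete_frequencies(com$linkage)$summary
#>         H1       H2 H3 H4 mean_biallelic_sites
#> 1 7.376686 92.62331  0  0                  499
```

The skewed TP1 mixture (0.8/0.2) sits at mean major-allele frequency
≈ 0.80, the even TP2 mixture nearer 0.5 and at higher π — strain evenness
is what drives both numbers. With recombination disabled no pair ever
shows four haplotypes (H4 = 0); `community_spec(..., recomb_rate = 0.5)`
makes H4 appear and r² decay with distance. Recovering the truth:

```r
w <- estimate_strain_fractions(
  derived_allele_frequencies(com$allele_counts, com$truth, "TP1"),
  com$truth$haplotypes)
round(w, 3)
#> [1] 0.796 0.204
```

Selecting focal populations from the bundled published abundance matrix:

```r
select_focal_mags(norp_rpkm_matrix())
#> Focal population selection
#>   persistent: NORP83, NORP139, NORP147, NORP163, NORP169, NORP246
#>   spike:      NORP6, NORP57, NORP100, NORP167
```

Six persistent populations and four single-sample spikes — the worked
example the acceptance checks pin down.

## Command line

An `exec/aquiferpop` script exposes subcommands
(`simulate`, `validate`, `abundance`, `diversity`, `recombination`,
`genefreq`, `dnds`), e.g.

```sh
aquiferpop simulate --out bundle/ --seed 7 --strains 3 --recomb 0.2
aquiferpop validate --dir bundle/
```

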