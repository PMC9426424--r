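---
title: "Population-genomic inference from metagenomic time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genomic inference from metagenomic time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquiferpop)
```

## The problem

A metagenome-assembled genome (MAG) recovered from an environmental sample
is not an organism: it is the composite of a population, usually a mixture
of closely related strains whose relative abundances drift over time. Given
a time series of metagenomes mapped against a set of MAGs, `aquiferpop`
answers a chain of questions about each population:

1. Which populations are abundant enough, often enough, to analyse at the
   nucleotide level (focal selection from RPKM)?
2. How diverse is each population, per site, per gene and genome-wide
   (SNV calling, nucleotide diversity $\pi$)?
3. Do strains recombine, or are lineages clonal (linkage disequilibrium
   decay, four-gamete test)?
4. Are there gene-specific selective sweeps or differentiated genomic
   regions (Welch low-$\pi$ scan, windowed Hudson $F_{ST}$)?
5. Which genes change in copy number as strains come and go
   (coverage-ratio gene frequency)?
6. What kind of selection acts on the variable genes (pairwise dN/dS)?

The package operates entirely on small text tables (per-site allele counts,
read-linked SNV pairs, per-gene coverages, GFF3, FASTA) so that it is
agnostic to the upstream mapper and profiler.

## Statistical definitions

**SNV calling.** A site is a single nucleotide variant when its allele-count
entropy is positive, its coverage is at least 20x, and the departure from
consensus $1 - \hat p_{\mathrm{major}}$ is at least 10%. The consensus is
the count-maximal nucleotide — the reference base in the assembly plays no
role — with ties broken in the fixed order A < C < G < T for determinism.
The coverage and departure thresholds are deliberately conservative; they
suppress mapping noise at the cost of missing rare alleles below 10%.

**Nucleotide diversity.** Per site,
$\pi = 1 - \sum_i \binom{c_i}{2} / \binom{n}{2}$ over nucleotide counts
$c_i$ with coverage $n$: the probability that two reads drawn without
replacement mismatch. We use the unbiased $\binom{n}{2}$ estimator rather
than $1 - \sum_i (c_i/n)^2$ because coverages near the 20x floor make the
plug-in estimator visibly biased. (Some descriptions phrase $\pi$ as the
probability of two reads *matching*; the implemented quantity is the
standard mismatch probability.) Gene and genome $\pi$ are means over all
covered positions; invariant positions contribute zero, so
`mean_pi(values, n_covered)` takes the number of covered sites explicitly
when only variable sites are stored.

**Allele-frequency matrices.** Rows are the union of SNV positions across
the time points of interest. Each row tracks the consensus allele of the
first time point where the site was called; cells where the site was
covered at ≥ 20x but not called are set to 1.0 (fixed-at-consensus
convention), and cells below 20x are masked. The anchoring rule (first
time point of interest) is a package choice — any fixed anchor makes the
trajectory comparable across columns; the display order is average-linkage
Euclidean clustering.

**Linkage and recombination.** For a pair of biallelic sites with
read-pair haplotype counts $(AB, Ab, aB, ab)$,
$r^2 = D^2 / f_A(1-f_A)f_B(1-f_B)$ with $D = f_{AB} - f_A f_B$. Pairs
monomorphic at either site within the linkage sample are excluded rather
than set to 0. Decay curves bin pair distances into closed 10-bp ranges
aligned at 1 bp and stratify by mutation type (S-S, N-S, N-N), where a
site is synonymous-typed if exchanging its two alleles in the codon of the
contig consensus preserves the amino acid. The four-gamete test counts
haplotypes present at ≥ 1 read pair (configurable; no published floor
exists, and the sensitivity to this threshold is worth checking on deep
data) and reports the percentage of pairs with 1–4 haplotypes; under
infinite sites a fourth haplotype requires recombination. Percentages are
averaged across time points of interest (a pooled mode is available,
since the published table caption is ambiguous on this point).

**Sweep scan.** Per gene and time point, a one-sided Welch $t$ test asks
whether the gene's per-site $\pi$ values (zeros included) are lower than
the genome-wide per-site values. We add Benjamini–Hochberg adjustment
across genes within each time point at $\alpha = 0.05$ — the source
procedure states no correction, so a raw-p mode is retained — and require
significance in *every* time point of interest (a pooled mode exists; the
per-time-point-then-intersect reading is implemented as the default).
Genes need at least 10 covered sites per time point to be tested; below
that, Welch's approximation is not defensible and the gene is reported as
untested rather than accepted or rejected.

**Hudson $F_{ST}$.** Per shared biallelic site,
$\mathrm{num} = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} -
\frac{p_2(1-p_2)}{n_2-1}$ and
$\mathrm{den} = p_1(1-p_2) + p_2(1-p_1)$, aggregated per gene as the ratio
of sums (never the mean of ratios). The per-site sample sizes are read
coverages. Windows of five consecutive eligible genes (complete start and
stop codon; coverage within 2 SD of the genome mean) slide with step 1;
windows whose mean exceeds the genome mean by 1 or 2 SD are merged into
regions when they overlap. Region counts are monotone non-increasing in
the SD threshold by construction. When several time-point pairs exist, the
default scan uses pair-averaged gene values; a per-pair mode is available.

**Gene frequency.** Gene coverage divided by the sample's median gene
coverage estimates copies per genome; genes whose range over the time
points of interest is ≥ 1 copy are "variable". Contigs shorter than
2.5 kb are excluded so that a contig is unlikely to consist of a single
ORF, which would make its genes incomparable to the genomic median.

**dN/dS.** The package computes pairwise dN/dS with the Nei–Gojobori
(1986) counting estimator with Jukes–Cantor correction, not a
maximum-likelihood codon model. This is a deliberate methodological
substitution: the counting estimator is fully specifiable and testable
against an independent pathway-enumeration oracle, whereas an ML estimator
would import an external optimizer as an un-checkable black box. Site
convention: mutations to stop codons are excluded from potential-site
fractions (nonsynonymous sites are $3L - S$, preserving $S + N = 3L$);
mutational pathways through stop codons are excluded from difference
averaging, falling back to all pathways in the rare case none is
stop-free. Pairs are filtered to $d_N > 0$, $0.01 < d_S < 1$ and
$d_N/d_S < 5$: the lower $d_S$ bound removes pairs too recently diverged
to say anything, the upper bound and ratio cap remove saturated or
unstable estimates. Gene categories ("below genome mean", "relaxed
( > 1)", "none") compare each gene's mean over retained pairs to the
genome-wide mean of per-gene means (a pair-pooled mean is available).

## The synthetic community generator

The generator is a *stated world*, not a fit to data: the study system is
observational and publishes no generative model, so every simulator choice
is a stand-in, chosen once and documented here.

* **Genealogy.** Strains follow a star genealogy under infinite sites:
  each discriminating SNV arises in exactly one strain, with no
  back-mutation. Consequently at most three of the four two-locus
  haplotypes can exist without recombination, making the fourth haplotype
  a recombination-only signal — exactly the property the four-gamete test
  assumes.
* **Coverage.** Sites are covered independently Poisson($\lambda w$),
  where $w$ is the mixture-weighted copy number at the site
  ($w = \sum_s f_s \cdot \mathrm{copy}_{s,g}$). Default $\lambda = 100$,
  comfortably above the 20x calling floor, matching the depth regime the
  selection criteria are designed to guarantee. No insert-size or GC
  structure is modelled.
* **Linkage.** Read pairs span two sites with Poisson intensity
  $\tfrac{\lambda}{2}\max(0, 1 - d/F)$ for distance $d$ and fragment
  length $F$ (default 300 bp, a typical short-read insert).
* **Recombination.** A spanning fragment re-assorts its second allele
  from an independently drawn strain with probability
  $1 - (1-\rho)^{d/100}$: $\rho$ (`recomb_rate`) is the re-assortment
  probability of a 100-bp pair. A distance-free per-pair probability
  cannot produce linkage *decay with distance*, which is one of the
  signals under test, so the rate is compounded per 100 bp; at $d = 100$
  it equals $\rho$ exactly, keeping the parameter interpretable. This is
  per-pair re-assortment, not a coalescent: it creates the four-gamete and
  decay signals at desk scale but has no notion of genealogy depth.
* **Sweeps and copy number.** Swept genes simply receive no
  discriminating sites (sweeps are imposed, not evolved). Multi-copy
  elements are coverage multipliers on gene intervals — the pipeline only
  ever sees coverage ratios, so modelling separate replicons would add
  nothing testable.
* **Error.** Sequencing error defaults to 0 so unit tests are crisp;
  setting it positive exercises the entropy/departure filters. Allowed
  range 0–1%.

What a green synthetic test establishes: that the estimators recover the
parameters of *this* world (mixture frequencies, copy numbers, presence of
re-assortment) at the stated depths. What it does not establish: behaviour
under mapping bias, conserved-region cross-mapping between sister
populations, or non-uniform coverage — none of which the generator
emulates.

The strain-fraction estimator solves
$\min_w \lVert H^\top w - \hat f \rVert^2$ on the simplex by exhaustive
active-set enumeration (at most $2^8$ equality-constrained solves), which
is exact on noiseless input; strains with identical haplotypes are merged
with a warning since no frequency data can separate them. It stands in
for full haplotype-deconvolution tools only as a truth-recovery check.

## Numerical and interface choices

* Positions are 0-based half-open internally; all human-facing report
  output is 1-based. `to_report_position()` is the single conversion
  point.
* Ties in major-allele calls break A < C < G < T; $r^2$ is clamped to
  $[0,1]$ against floating-point spill; Welch's statistic is computed in
  closed form so zero-variance degenerate inputs give deterministic
  p-values (1 when means are equal) instead of an error.
* Multi-allelic (3–4 allele) sites are excluded from linkage by the
  biallelic pair invariant; `validate_bundle()` flags pairs that
  reference them.
* RPKM is reads / ((MAG length / 10³) × (sample bp / 10⁶)); the
  sample-size denominator is total base pairs sequenced, per the unit's
  name. Abundance thresholds (≥ 5, ≥ 30 RPKM) are inclusive.
* All thresholds live in one `run_config()` object whose defaults are the
  workflow's published stringency; a text config file round-trips it.

## Worked example

```{r example, eval = FALSE}
fr <- rbind(TP1 = c(0.8, 0.2), TP2 = c(0.3, 0.7))
com <- generate_community(community_spec(fr, snv_density = 10),
                          sim_config(seed = 1))
snvs <- call_snvs(com$allele_counts)
gamete_frequencies(com$linkage)$summary
w <- estimate_strain_fractions(
  derived_allele_frequencies(com$allele_counts, com$truth, "TP1"),
  com$truth$haplotypes)
```

## Known limitations

* The Welch scan tests sites as independent observations; linked sites
  within a gene violate independence, which the conservative thresholds
  only partially offset.
* The NG86 estimator saturates near $p = 3/4$ and drops such pairs; on
  very divergent haplotype sets the retained-pair mean is a biased-down
  summary.
* The generator's independent-site Poisson coverage understates the
  variance of real coverage; recovery RMSEs measured on it are
  best-case.
* `estimate_strain_fractions` requires known haplotypes; it does not
  infer them.
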