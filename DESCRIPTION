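Package: aquiferpop
Title: Population Genomics of Microbial Metagenome Time Series
Version: 0.1.0
Authors@R:
    person("North Pond", "Pipeline Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for intraspecific population-genomic inference from
    metagenomic time series of microbial communities: focal-population
    selection from length- and depth-normalized coverage (RPKM), single
    nucleotide variant calling from per-site allele counts with entropy,
    coverage and departure-from-consensus filters, nucleotide diversity (pi)
    per site, gene and genome, major-allele-frequency matrices with a
    fixed-site convention, linkage disequilibrium (r^2) decay curves and the
    four-gamete test from read-linked SNV pairs, gene-specific selective
    sweep detection via Welch's t test on per-gene diversity, sliding-window
    Hudson F_ST scans, coverage-ratio gene copy-number variation, and
    pairwise Nei-Gojobori dN/dS with divergence filters. Includes a
    ground-truthed synthetic strain-mixture community generator emitting the
    exact tables the pipeline consumes, plus a constrained least-squares
    strain-fraction estimator for truth recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
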