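Package: pmdscape
Title: Segmentation and Cohort Analysis of Partially Methylated Domains in
    WGBS Methylomes
Version: 0.1.0
Authors@R:
    person("pmdscape", "developers", email = "pmdscape@example.org",
           role = c("aut", "cre"))
Description: Tools for segmenting whole-genome bisulfite sequencing (WGBS)
    methylomes into partially methylated domains (PMDs) using windowed
    mean-constrained beta-binomial polarization scores decoded with a
    two-state hidden Markov model, and for cohort-level analysis of the
    resulting domain calls: genome-fraction and frequency statistics with
    interval-shuffle permutation nulls, CpG-island hypermethylation (CIMP)
    quantification with beta regression against PMD content, gene-set
    exclusion testing by hypergeometric tail probabilities, methylome tiling,
    hierarchical clustering and principal component analysis. Includes a
    seeded synthetic-methylome generator with planted domains and full ground
    truth for validation of every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
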