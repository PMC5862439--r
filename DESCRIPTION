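Package: rohselect
Title: Runs of Homozygosity and Selection-Signature Analysis for Breeding Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how sustained artificial selection reshapes
    autozygosity in a livestock cohort. Provides a forward-time pedigree
    simulator with exact identity-by-descent tracking, VCF genotype input with
    the standard hard filters, a deterministic run-based caller for runs of
    homozygosity (ROH), genome-wide autozygosity coefficients (F_roh, F_snp),
    linkage-disequilibrium pruning and decay curves, a VanRaden genomic
    relationship matrix, EHH/iHS haplotype selection scans with frequency-bin
    standardization, 10-Mb bin association models (logistic ROH-status trend
    over selection rounds, and a kinship REML mixed model for ROH length
    against body weight), and maximal-overlap ROH region detection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
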