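Package: cardiotrio
Title: Trio-Sequencing Rare-Variant Analysis for Congenital Heart Disease Cohorts
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for rare-variant analysis of
    parent-offspring trio sequencing cohorts. Implements a
    trinucleotide-context de novo mutation expectation model with
    frameshift and coverage rules, Poisson-framework de novo mutation
    burden tests overall and within gene sets, the trio variant
    prioritization cascade (de novo, homozygous recessive, compound
    heterozygous, ultra-rare damaging, and pseudocontrols built from
    untransmitted parental alleles), carrier-collapsing case/control
    burden tests with exact proportion confidence intervals, copy-number
    variant interval algebra (reciprocal overlap, de novo CNV
    classification, copy-number variable regions, minimal critical
    regions, mosaic flagging), and hypergeometric enrichment of candidate
    gene sets in single-cell coexpression modules with
    Benjamini-Hochberg FDR. A synthetic trio-cohort generator with
    planted ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    withr
Config/testthat/edition: 3
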