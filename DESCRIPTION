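Package: mitoburden
Title: Case-Control Burden and Pathogenicity Analysis of Mitochondrial
    Genome Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for case-control analysis of
    mitochondrial DNA substitutions called from deep sequencing.  Reads
    per-sample variant tables (TSV or VCF) carrying mutant-read and total-read
    counts, computes heteroplasmic fractions, groups alleles by cohort sharing
    and tests per-gene carrier enrichment (Pearson chi-square or Fisher exact,
    chosen by an expected-count rule), runs a burden-ratio-stratified sequence
    kernel association test (SKAT) with moment-matching, characteristic-function
    and permutation p-values, annotates protein alleles by combining three
    pathogenicity-tool ratings and tRNA alleles by a population-frequency,
    conservation-index and cloverleaf-structure criterion, and compares
    clinical phenotypes between carriers and non-carriers.  A synthetic-cohort
    generator reproduces the statistical structure of the intended study design
    so the whole pipeline is testable without access to protected cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    broom,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
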