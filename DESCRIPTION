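Package: ppmscreen
Title: Predictive Promoter Models from Homotypic Binding-Site Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates predictive promoter models (PPMs) based on
    distance-constrained homotypic transcription-factor binding-site pairs in
    TSS-proximal windows, with the HMX1 site (canonical CAAGTG, core CAAG) as
    the default motif. Provides promoter window extraction from genome FASTA
    and transcript tables, exact both-strand motif scanning, admissible-pair
    enumeration under a spacing constraint, tiered model classification,
    enrichment statistics (Fisher's exact test, exact binomial confidence
    intervals for sensitivity and specificity, chi-squared with Yates
    correction for pathway over-representation), genome-wide screening with
    cross-species conservation and pair co-occurrence filters, and seeded
    synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
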