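Package: equicnv
Title: Multi-Algorithm CNV Consensus, Enrichment and Body-Size Association for SNP-Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative copy-number-variant (CNV) analysis from
    SNP-array call sets in horses and other livestock. Reads CNV call tables
    from multiple detection algorithms (PennCNV-, QuantiSNP- and
    CNVPartition-style dialects, generic TSV and BED), applies per-sample and
    per-call quality filters, merges calls into CNV regions, forms a
    three-level (population, breed, individual) multi-caller consensus,
    computes per-chromosome SNP-density enrichment with an optional
    permutation test, summarises CNV sharing among breeds, tests CNV regions
    for association with a quantitative trait using a breed-adjusted linear
    model with max-statistic permutation, and validates copy numbers from
    qPCR Ct tables by the 2^-ddCt method. A seeded synthetic-data generator
    emulates a breed-structured cohort with three caller error profiles for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
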