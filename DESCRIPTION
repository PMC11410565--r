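Package: germtriage
Title: Hybrid Germline Cancer-Variant Triage for Population Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for secondary-findings triage of rare germline variants in
    the 28 cancer genes of the ACMG SF v3.0 reporting list. Implements the
    pre-triage filtration cascade (panel, consequence, gnomAD allele
    frequency, ClinVar benign removal), a deterministic ACMG/AMP 2015
    criterion-combination engine, an in-silico predictor consensus rule
    (SIFT, PolyPhen2-HDIV, MutationAssessor, M-CAP, CADD, resolved by REVEL
    and MetaLR), a ClinVar-review-status-aware triage decision tree with an
    emulated manual-review step producing deleterious-VUS calls, a
    proto-oncogene (RET/MAX) loss-of-function exclusion, and cohort
    prevalence, gene-constraint (pLI/LOEUF), and geographic summaries.
    Includes a seeded Hardy-Weinberg synthetic-cohort generator with planted
    truth labels so every pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    readr,
    rlang,
    withr,
    ggplot2,
    generics,
    jsonlite,
    vcfR,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
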