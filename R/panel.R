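#' The 28-gene ACMG SF v3.0 cancer panel
#'
#' Gene symbols of the 28 cancer-predisposition genes on the ACMG SF v3.0
#' secondary-findings reporting list. All 28 are autosomal.
#'
#' @return Character vector of 28 gene symbols.
#' @export
#' @examples
#' acmg_sf_genes()
acmg_sf_genes <- function() {
  c(
    "APC", "BMPR1A", "BRCA1", "BRCA2", "MAX", "MEN1", "MLH1", "MSH2",
    "MSH6", "MUTYH", "NF2", "PALB2", "PMS2", "PTEN", "RB1", "RET",
    "SDHAF2", "SDHB", "SDHC", "SDHD", "SMAD4", "STK11", "TMEM127",
    "TP53", "TSC1", "TSC2", "VHL", "WT1"
  )
}

#' Bundled gnomAD v2.1.1-style gene constraint table
#'
#' Per-gene pLI and LOEUF constraint metrics for the 28-gene panel, as used
#' for the conserved/nonconserved stratification (conserved means
#' LOEUF < 0.35). Shipped as a plain TSV under `extdata`; pass your own
#' table with the same columns to override.
#'
#' @return Tibble with columns `gene`, `pli`, `loeuf`.
#' @export
#' @examples
#' default_constraint_table()
default_constraint_table <- function() {
  path <- system.file("extdata", "gene_constraint_gnomad211.tsv",
                      package = "germtriage", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(),
    pli = readr::col_double(),
    loeuf = readr::col_double()
  ))
}

# enum token sets used by readers and the triage tree
functional_classes <- function() {
  c("nonsynonymous_SNV", "stop_gain", "frameshift_deletion",
    "frameshift_insertion", "splice_site", "synonymous", "other")
}

truncating_classes <- function() {
  c("stop_gain", "frameshift_deletion", "frameshift_insertion", "splice_site")
}

clinvar_classes <- function() {
  c("P", "LP", "P_LP", "VUS", "conflicting", "not_provided",
    "B", "LB", "not_submitted")
}

clinvar_statuses <- function() {
  c("expert_panel", "multiple_submitters", "single_submitter",
    "no_assertion", "not_submitted")
}

gof_lof_labels <- function() c("GoF", "LoF", "unknown")

# pathogenic-or-likely-pathogenic ClinVar classes (the combined P_LP token
# is a single ClinVar record carrying both assertions)
plp_classes <- function() c("P", "LP", "P_LP")
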