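#' Filtration settings
#'
#' Configuration for the pre-triage filtration cascade: panel restriction,
#' consequence filter, gnomAD population-frequency filter, and ClinVar
#' benign removal.
#'
#' The frequency filter drops variants with gnomAD AF strictly above
#' `af_max`; a variant exactly at the boundary, or absent from gnomAD, is
#' kept (absence from a population database is itself evidence of rarity).
#'
#' @param panel_genes Genes to keep (default the 28-gene ACMG SF v3.0 panel).
#' @param af_max Maximum gnomAD allele frequency to keep (default 0.05).
#' @param allowed_classes Functional classes to keep (default nonsynonymous
#'   SNVs, stop-gains, frameshift indels, and splice-site variants;
#'   synonymous substitutions are thereby removed).
#' @return A `filter_config` list.
#' @export
filter_config <- function(panel_genes = acmg_sf_genes(),
                          af_max = 0.05,
                          allowed_classes = c(
                            "nonsynonymous_SNV", "stop_gain",
                            "frameshift_deletion", "frameshift_insertion",
                            "splice_site"
                          )) {
  stopifnot(length(panel_genes) > 0L, af_max > 0, af_max <= 1)
  .check_enum(allowed_classes, functional_classes(), "functional_class")
  structure(
    list(panel_genes = panel_genes, af_max = af_max,
         allowed_classes = allowed_classes),
    class = "filter_config"
  )
}

#' Apply the pre-triage filtration cascade
#'
#' Partitions annotated variants into kept and dropped sets. Each dropped
#' variant carries the first failing reason in the fixed cascade order:
#' `off_panel`, then `disallowed_class` (synonymous and other non-coding
#' consequences), then `af_above_max` (gnomAD AF above the 5% default
#' cut), then `clinvar_benign` (ClinVar benign or likely benign). The
#' cascade is deterministic and order-stable, and the two output sets
#' partition the input.
#'
#' @param annotations Annotation tibble from [read_annotation_table()].
#' @param config A [filter_config()].
#' @return The input tibble with two extra columns: `kept` (logical) and
#'   `drop_reason` (NA for kept rows).
#' @export
apply_filters <- function(annotations, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  annotations <- tibble::as_tibble(annotations)
  reason <- dplyr::case_when(
    !(annotations$gene %in% config$panel_genes) ~ "off_panel",
    !(annotations$functional_class %in% config$allowed_classes) ~
      "disallowed_class",
    !is.na(annotations$gnomad_af) & annotations$gnomad_af > config$af_max ~
      "af_above_max",
    annotations$clinvar_class %in% c("B", "LB") ~ "clinvar_benign",
    TRUE ~ NA_character_
  )
  annotations$kept <- is.na(reason)
  annotations$drop_reason <- reason
  annotations
}

#' Tally dropped variants by reason
#'
#' @param filtered Output of [apply_filters()] (or just its dropped rows).
#' @return Tibble with columns `drop_reason` and `n`, one row per cascade
#'   reason (zero counts included); counts sum to the number of dropped rows.
#' @export
filter_report <- function(filtered) {
  reasons <- c("off_panel", "disallowed_class", "af_above_max",
               "clinvar_benign")
  dropped <- filtered[!is.na(filtered$drop_reason), , drop = FALSE]
  counts <- table(factor(dropped$drop_reason, levels = reasons))
  tibble::tibble(drop_reason = reasons, n = as.integer(counts))
}
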