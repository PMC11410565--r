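#' Route filtered variants through the ClinVar x engine decision tree
#'
#' Assigns each variant one of three routes in fixed priority order:
#' \enumerate{
#'   \item ClinVar P/LP with expert-panel or multiple-submitters review
#'     status, confirmed pathogenic/likely-pathogenic by the criterion
#'     engine: reported automatically (`auto_report`).
#'   \item ClinVar P/LP with only single-submitter or no-assertion status:
#'     sent to manual review regardless of the engine tier.
#'   \item ClinVar VUS, conflicting, not-provided, or never submitted, but
#'     pathogenic/likely pathogenic per the engine: manual review.
#'   \item ClinVar P/LP at high review status that the engine nevertheless
#'     calls uncertain: manual review (automated criteria sometimes
#'     under-call even expert-panel variants).
#'   \item Anything else: discarded.
#' }
#' ClinVar benign/likely-benign variants must have been removed by the
#' filters and raise an error here.
#'
#' @param annotations Filtered annotation tibble (kept rows only).
#' @param engine_tier Character vector of [combine_acmg()] tiers, one per row.
#' @return Tibble with columns `variant_id`, `route`, `route_rule`.
#' @export
route_variants <- function(annotations, engine_tier) {
  stopifnot(nrow(annotations) == length(engine_tier))
  if (any(annotations$clinvar_class %in% c("B", "LB"))) {
    stop("benign/likely-benign variants reached triage; ",
         "run apply_filters() first", call. = FALSE)
  }
  plp <- annotations$clinvar_class %in% plp_classes()
  high_status <- annotations$clinvar_status %in%
    c("expert_panel", "multiple_submitters")
  low_status <- annotations$clinvar_status %in%
    c("single_submitter", "no_assertion")
  vus_like <- annotations$clinvar_class %in%
    c("VUS", "conflicting", "not_provided", "not_submitted")
  engine_plp <- engine_tier %in% c("pathogenic", "likely_pathogenic")
  rule <- dplyr::case_when(
    plp & engine_plp & high_status ~ "clinvar_engine_concordant_confident",
    plp & low_status ~ "clinvar_plp_low_review_status",
    vus_like & engine_plp ~ "engine_plp_clinvar_unsettled",
    plp & high_status & engine_tier == "uncertain" ~
      "engine_uncertain_clinvar_confident",
    TRUE ~ "no_pathogenic_signal"
  )
  route <- dplyr::case_when(
    rule == "clinvar_engine_concordant_confident" ~ "auto_report",
    rule == "no_pathogenic_signal" ~ "discard",
    TRUE ~ "manual_review"
  )
  tibble::tibble(variant_id = annotations$variant_id,
                 route = route, route_rule = rule)
}

#' Emulated manual review of prioritized variants
#'
#' Deterministic stand-in for the expert review step, driven by recorded
#' evidence: the engine tier, the in-silico consensus verdict, and a
#' boolean literature-support flag. Rules, in order:
#' \enumerate{
#'   \item Variants never submitted to ClinVar that the engine calls
#'     P/LP become deleterious VUS (`del_VUS`) always: novel variants lack
#'     the clinical data needed for a P/LP assertion.
#'   \item ClinVar P/LP at single-submitter/no-assertion status with
#'     in-silico support and literature support are confirmed: `PV` when
#'     ClinVar says pathogenic, `LPV` otherwise (the combined P/LP class
#'     is conservatively treated as likely pathogenic).
#'   \item ClinVar P/LP with in-silico support but no literature support
#'     are downgraded to `del_VUS`.
#'   \item ClinVar VUS/conflicting/not-provided variants that the engine
#'     calls P/LP with in-silico support become `del_VUS`.
#'   \item Everything else is `excluded`.
#' }
#' In-silico support means a `supported` or `conflicting_resolved_supported`
#' consensus verdict.
#'
#' @param annotations Annotation rows routed to manual review.
#' @param engine_tier Engine tiers for those rows.
#' @param verdict Consensus verdicts ([insilico_consensus()]) for those rows.
#' @param route Routes from [route_variants()]; all must be
#'   `manual_review`, otherwise an error is raised.
#' @return Tibble with columns `variant_id`, `final_tier`, `review_rule`.
#' @export
emulate_manual_review <- function(annotations, engine_tier, verdict, route) {
  if (any(route != "manual_review")) {
    stop("emulate_manual_review() called on non-manual route", call. = FALSE)
  }
  stopifnot(nrow(annotations) == length(engine_tier),
            nrow(annotations) == length(verdict))
  novel <- annotations$clinvar_status == "not_submitted"
  plp <- annotations$clinvar_class %in% plp_classes()
  low_status <- annotations$clinvar_status %in%
    c("single_submitter", "no_assertion")
  vus_like <- annotations$clinvar_class %in%
    c("VUS", "conflicting", "not_provided")
  engine_plp <- engine_tier %in% c("pathogenic", "likely_pathogenic")
  supported <- verdict %in% .supporting_verdicts()
  lit <- annotations$literature_support
  rule <- dplyr::case_when(
    novel & engine_plp ~ "novel_engine_plp_to_delvus",
    plp & low_status & supported & lit ~ "clinvar_plp_confirmed",
    plp & supported & !lit ~ "clinvar_plp_no_literature_to_delvus",
    vus_like & engine_plp & supported ~ "vus_engine_plp_supported_to_delvus",
    TRUE ~ "insufficient_evidence_excluded"
  )
  final_tier <- dplyr::case_when(
    rule == "novel_engine_plp_to_delvus" ~ "del_VUS",
    rule == "clinvar_plp_confirmed" &
      annotations$clinvar_class == "P" ~ "PV",
    rule == "clinvar_plp_confirmed" ~ "LPV",
    rule %in% c("clinvar_plp_no_literature_to_delvus",
                "vus_engine_plp_supported_to_delvus") ~ "del_VUS",
    TRUE ~ "excluded"
  )
  tibble::tibble(variant_id = annotations$variant_id,
                 final_tier = final_tier, review_rule = rule)
}

#' Proto-oncogene loss-of-function exclusion
#'
#' RET and MAX are the only proto-oncogenes on the panel; their cancer
#' driver mechanism is gain of function, so variants with proven or
#' potential loss of function of the encoded protein are excluded from the
#' general prevalence analysis. "Proven" means an explicit `LoF` label;
#' "potential" means no label and a truncating consequence (stop-gain,
#' frameshift, splice site). Variants labelled `GoF` stay eligible.
#'
#' @param decisions Triage decision tibble (needs `variant_id`,
#'   `prevalence_eligible`, `evidence_trail`).
#' @param annotations Annotation tibble with `gene`, `gof_lof`,
#'   `functional_class`.
#' @return `decisions` with `prevalence_eligible` and `evidence_trail`
#'   updated where the rule fires.
#' @export
protooncogene_exclusion <- function(decisions, annotations) {
  ann <- annotations[match(decisions$variant_id, annotations$variant_id), ]
  fires <- ann$gene %in% c("RET", "MAX") &
    (ann$gof_lof == "LoF" |
       (ann$gof_lof == "unknown" &
          ann$functional_class %in% truncating_classes()))
  fires[is.na(fires)] <- FALSE
  decisions$prevalence_eligible[fires] <- FALSE
  decisions$evidence_trail[fires] <- paste0(
    decisions$evidence_trail[fires], ";protooncogene_lof_excluded")
  decisions
}

#' Full triage of a filtered cohort
#'
#' Runs the criterion engine, the in-silico consensus, the routing tree,
#' the emulated manual review, and the proto-oncogene exclusion over the
#' kept rows of a filtered annotation table. Auto-reported variants take
#' their tier from the ClinVar class (`PV` for pathogenic, `LPV`
#' otherwise); discarded variants are `excluded`.
#'
#' @param filtered Output of [apply_filters()]; only rows with
#'   `kept == TRUE` are triaged.
#' @param apply_protooncogene_rule Apply [protooncogene_exclusion()]
#'   (default TRUE).
#' @return Tibble with one row per kept variant: `variant_id`, `gene`,
#'   `engine_tier`, consensus columns, `route`, `final_tier`, `novel`,
#'   `prevalence_eligible`, and a semicolon-joined `evidence_trail`.
#' @export
triage_cohort <- function(filtered, apply_protooncogene_rule = TRUE) {
  stopifnot("kept" %in% names(filtered))
  ann <- filtered[filtered$kept, , drop = FALSE]
  engine_tier <- combine_acmg(ann$acmg_flags)
  cons <- insilico_consensus(ann)
  routing <- route_variants(ann, engine_tier)
  decisions <- tibble::tibble(
    variant_id = ann$variant_id,
    gene = ann$gene,
    engine_tier = engine_tier,
    consensus = cons$verdict,
    votes_deleterious = cons$votes_deleterious,
    votes_available = cons$votes_available,
    route = routing$route,
    final_tier = NA_character_,
    novel = ann$clinvar_status == "not_submitted",
    evidence_trail = paste0("route:", routing$route_rule)
  )
  auto <- decisions$route == "auto_report"
  decisions$final_tier[auto] <-
    ifelse(ann$clinvar_class[auto] == "P", "PV", "LPV")
  decisions$evidence_trail[auto] <-
    paste0(decisions$evidence_trail[auto], ";tier:auto_clinvar_class")
  decisions$final_tier[decisions$route == "discard"] <- "excluded"
  man <- decisions$route == "manual_review"
  if (any(man)) {
    review <- emulate_manual_review(
      ann[man, , drop = FALSE], engine_tier[man], cons$verdict[man],
      decisions$route[man]
    )
    decisions$final_tier[man] <- review$final_tier
    decisions$evidence_trail[man] <-
      paste0(decisions$evidence_trail[man], ";review:", review$review_rule)
  }
  decisions$prevalence_eligible <- decisions$final_tier != "excluded"
  if (apply_protooncogene_rule) {
    decisions <- protooncogene_exclusion(decisions, ann)
  }
  decisions
}

#' Descriptive summary of GoF/LoF variant positions within a protein
#'
#' Summarizes where gain-of-function and loss-of-function substitutions
#' sit along the protein: per-label count, median residue, residue range,
#' and median distance from the protein midpoint (central clustering pulls
#' this down). Purely descriptive; no inferential claim is made.
#'
#' @param annotations Annotation rows for one gene, with a `gof_lof` column.
#' @param protein_positions Named integer vector mapping `variant_id` to
#'   residue index; required for every summarized variant.
#' @param protein_length Protein length in residues (for the midpoint);
#'   defaults to the maximum supplied residue.
#' @return Tibble with one row per label present among `GoF`/`LoF`; labels
#'   with no variants are omitted (with a message).
#' @export
gof_lof_position_summary <- function(annotations, protein_positions,
                                     protein_length = NULL) {
  if (length(unique(annotations$gene)) > 1L) {
    stop("summarize one gene at a time", call. = FALSE)
  }
  labelled <- annotations[annotations$gof_lof %in% c("GoF", "LoF"), ,
                          drop = FALSE]
  missing_pos <- setdiff(labelled$variant_id, names(protein_positions))
  if (length(missing_pos) > 0L) {
    stop("no residue position for: ", paste(missing_pos, collapse = ", "),
         call. = FALSE)
  }
  labelled$residue <- unname(protein_positions[labelled$variant_id])
  if (is.null(protein_length)) {
    protein_length <- max(labelled$residue, 1L)
  }
  mid <- protein_length / 2
  for (lab in c("GoF", "LoF")) {
    if (!any(labelled$gof_lof == lab)) {
      message("no ", lab, "-labelled variants; group omitted")
    }
  }
  labelled |>
    dplyr::group_by(.data$gof_lof) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_residue = stats::median(.data$residue),
      residue_min = min(.data$residue),
      residue_max = max(.data$residue),
      residue_range = max(.data$residue) - min(.data$residue),
      median_dist_from_center = stats::median(abs(.data$residue - mid)),
      .groups = "drop"
    )
}
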