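test_that("the routing tree follows its priority order", {
  cases <- dplyr::bind_rows(
    make_ann(pos = 1, clinvar_class = "P",
             clinvar_status = "multiple_submitters"),
    make_ann(pos = 2, clinvar_class = "VUS",
             clinvar_status = "single_submitter"),
    make_ann(pos = 3, clinvar_class = "not_submitted",
             clinvar_status = "not_submitted"),
    make_ann(pos = 4, clinvar_class = "LP",
             clinvar_status = "single_submitter"),
    make_ann(pos = 5, clinvar_class = "P",
             clinvar_status = "expert_panel"),
    make_ann(pos = 6, clinvar_class = "conflicting",
             clinvar_status = "no_assertion")
  )
  tiers <- c("pathogenic", "uncertain", "likely_pathogenic",
             "benign", "uncertain", "pathogenic")
  out <- route_variants(cases, tiers)
  expect_equal(out$route,
               c("auto_report",   # P + high status + engine pathogenic
                 "discard",       # VUS + engine uncertain
                 "manual_review", # novel + engine LP
                 "manual_review", # P/LP at single-submitter status
                 "manual_review", # expert panel but engine uncertain
                 "manual_review"))# conflicting + engine pathogenic
  expect_error(
    route_variants(make_ann(clinvar_class = "B"), "uncertain"),
    "benign"
  )
})

test_that("manual review applies its deterministic rules", {
  novel <- make_ann(pos = 10, clinvar_class = "not_submitted",
                    clinvar_status = "not_submitted",
                    functional_class = "stop_gain")
  out <- emulate_manual_review(novel, "pathogenic", "supported",
                               "manual_review")
  expect_equal(out$final_tier, "del_VUS")

  lp <- make_ann(pos = 11, clinvar_class = "LP",
                 clinvar_status = "single_submitter",
                 literature_support = TRUE)
  out <- emulate_manual_review(lp, "likely_pathogenic", "supported",
                               "manual_review")
  expect_equal(out$final_tier, "LPV")

  p <- make_ann(pos = 12, clinvar_class = "P",
                clinvar_status = "no_assertion", literature_support = TRUE)
  out <- emulate_manual_review(p, "pathogenic",
                               "conflicting_resolved_supported",
                               "manual_review")
  expect_equal(out$final_tier, "PV")

  no_lit <- make_ann(pos = 13, clinvar_class = "P",
                     clinvar_status = "single_submitter")
  out <- emulate_manual_review(no_lit, "pathogenic", "supported",
                               "manual_review")
  expect_equal(out$final_tier, "del_VUS")

  vus <- make_ann(pos = 14, clinvar_class = "VUS")
  out <- emulate_manual_review(vus, "likely_pathogenic", "supported",
                               "manual_review")
  expect_equal(out$final_tier, "del_VUS")

  weak <- make_ann(pos = 15, clinvar_class = "VUS")
  out <- emulate_manual_review(weak, "likely_pathogenic", "not_supported",
                               "manual_review")
  expect_equal(out$final_tier, "excluded")

  expect_error(
    emulate_manual_review(vus, "uncertain", "supported", "discard"),
    "non-manual"
  )
})

test_that("RET/MAX loss-of-function variants lose prevalence eligibility", {
  ann <- dplyr::bind_rows(
    make_ann(pos = 21, gene = "RET", functional_class = "stop_gain"),
    make_ann(pos = 22, gene = "RET", gof_lof = "GoF"),
    make_ann(pos = 23, gene = "BRCA1", functional_class = "stop_gain"),
    make_ann(pos = 24, gene = "MAX", gof_lof = "LoF"),
    make_ann(pos = 25, gene = "MAX", functional_class = "nonsynonymous_SNV")
  )
  decisions <- tibble::tibble(
    variant_id = ann$variant_id,
    prevalence_eligible = TRUE,
    evidence_trail = "route:test"
  )
  out <- protooncogene_exclusion(decisions, ann)
  expect_equal(out$prevalence_eligible, c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_match(out$evidence_trail[1], "protooncogene_lof_excluded")
})

test_that("position summaries separate central from peripheral variants", {
  ann <- make_ann(n = 4, gene = "RET",
                  gof_lof = c("GoF", "GoF", "LoF", "LoF"))
  pos <- stats::setNames(c(500L, 520L, 80L, 1000L), ann$variant_id)
  out <- gof_lof_position_summary(ann, pos, protein_length = 1100L)
  expect_equal(out$residue_range[out$gof_lof == "GoF"], 20L)
  expect_equal(out$residue_range[out$gof_lof == "LoF"], 920L)

  one <- make_ann(n = 2, gene = "RET", gof_lof = "GoF")
  pos1 <- stats::setNames(c(300L, 310L), one$variant_id)
  expect_message(res <- gof_lof_position_summary(one, pos1), "LoF")
  expect_equal(nrow(res), 1L)

  # planted clustering: central GoF vs scattered LoF
  set.seed(77)
  n <- 30
  planted <- make_ann(n = 2 * n, gene = "RET",
                      gof_lof = rep(c("GoF", "LoF"), each = n))
  L <- 1114L
  residues <- c(round(stats::runif(n, L / 2 - 80, L / 2 + 80)),
                round(stats::runif(n / 2, 1, 150)),
                round(stats::runif(n / 2, L - 150, L)))
  names(residues) <- planted$variant_id
  res <- gof_lof_position_summary(planted, residues, protein_length = L)
  expect_lt(res$median_dist_from_center[res$gof_lof == "GoF"],
            res$median_dist_from_center[res$gof_lof == "LoF"])

  expect_error(gof_lof_position_summary(planted, residues[-1]),
               "no residue position")
})

test_that("triage of the synthetic cohort recovers every planted label", {
  co <- small_sim(seed = 23, n_samples = 100, n_variants = 150)
  filtered <- apply_filters(co$annotations)
  decisions <- triage_cohort(filtered)
  truth <- co$truth[is.na(co$truth$expected_filter_reason), ]
  joined <- dplyr::inner_join(truth, decisions, by = "variant_id")
  expect_equal(nrow(joined), nrow(truth))
  expect_equal(joined$route, joined$expected_route)
  expect_equal(joined$final_tier, joined$expected_tier)
  # auto-reported planted cases all land in auto_report; novel engine-P/LP
  # all land in del_VUS
  expect_true(all(joined$route[joined$category %in%
                                 c("auto_pv", "auto_lpv")] == "auto_report"))
  expect_true(all(joined$final_tier[joined$category == "novel_delvus"] ==
                    "del_VUS"))
  expect_true(all(nchar(joined$evidence_trail) > 0))
  # determinism: identical inputs, identical decision table
  expect_identical(decisions, triage_cohort(filtered))
})
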