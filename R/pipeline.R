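#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Pipeline configuration
#'
#' Bundles the input paths and settings for [run_pipeline()].
#'
#' @param vcf Path to the cohort VCF.
#' @param annotations Path to the annotation TSV.
#' @param samples Path to the sample metadata TSV.
#' @param constraint Path to a gene constraint TSV (`gene`, `pli`,
#'   `loeuf`); `NULL` uses the bundled gnomAD v2.1.1-style table.
#' @param filters A [filter_config()].
#' @param carrier_tiers Tiers for the headline carrier fraction
#'   (default `PV`, `LPV`).
#' @param region_tiers Tiers for the regional carrier summary
#'   (default `PV`, `LPV`, `del_VUS`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(vcf, annotations, samples, constraint = NULL,
                            filters = filter_config(),
                            carrier_tiers = c("PV", "LPV"),
                            region_tiers = c("PV", "LPV", "del_VUS")) {
  for (p in c(vcf, annotations, samples, constraint)) {
    if (!file.exists(p)) stop("input not found: ", p, call. = FALSE)
  }
  structure(
    list(vcf = vcf, annotations = annotations, samples = samples,
         constraint = constraint, filters = filters,
         carrier_tiers = carrier_tiers, region_tiers = region_tiers),
    class = "pipeline_config"
  )
}

#' Run the full triage pipeline
#'
#' Orchestrates the stages in order: read inputs, filtration cascade,
#' criterion engine + in-silico consensus + triage tree + proto-oncogene
#' exclusion, prevalence statistics, constraint stratification, and
#' geographic summaries. A machine-readable manifest records input MD5
#' hashes, the filter settings, and per-stage counts, so identical inputs
#' give identical manifests.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `germtriage_run`: list with `filtered`,
#'   `filter_report`, `decisions`, `prevalence`, `class_table`,
#'   `gene_summary`, `group_totals`, `carrier_fraction`, `regional`,
#'   `migration`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- run_stage("read_vcf", read_cohort_vcf(config$vcf))
  ann <- run_stage("read_annotations",
                   read_annotation_table(config$annotations))
  samples <- run_stage("read_samples", read_sample_metadata(config$samples))
  constraint <- if (is.null(config$constraint)) {
    default_constraint_table()
  } else {
    readr::read_tsv(config$constraint, col_types = "cdd")
  }
  unmatched <- setdiff(cohort$variants$variant_id, ann$variant_id)
  if (length(unmatched) > 0L) {
    stop("pipeline stage 'join' failed: VCF variant(s) without annotation: ",
         paste(utils::head(unmatched, 5), collapse = ", "), call. = FALSE)
  }
  ann <- ann[ann$variant_id %in% cohort$variants$variant_id, , drop = FALSE]

  filtered <- run_stage("filters", apply_filters(ann, config$filters))
  freport <- filter_report(filtered)
  decisions <- run_stage("triage", triage_cohort(filtered))
  prevalence <- run_stage(
    "prevalence",
    prevalence_table(decisions, cohort$dosage)
  )
  class_table <- functional_class_table(decisions, ann)
  gene_summary <- run_stage(
    "constraint",
    gene_constraint_summary(gene_allele_totals(prevalence), constraint)
  )
  group_totals <- constraint_group_totals(gene_summary)
  carrier <- carrier_fraction(decisions, cohort$dosage,
                              tiers = config$carrier_tiers)
  regional <- regional_summary(samples, decisions, cohort$dosage,
                               tiers = config$region_tiers)
  migration <- migration_matrix(samples)

  manifest <- list(
    inputs = lapply(
      list(vcf = config$vcf, annotations = config$annotations,
           samples = config$samples),
      function(p) unname(tools::md5sum(p))
    ),
    filters = list(
      af_max = config$filters$af_max,
      allowed_classes = config$filters$allowed_classes,
      n_panel_genes = length(config$filters$panel_genes)
    ),
    counts = list(
      variants_in = nrow(ann),
      kept = sum(filtered$kept),
      dropped = sum(!filtered$kept),
      dropped_by_reason = stats::setNames(as.list(freport$n),
                                          freport$drop_reason),
      auto_report = sum(decisions$route == "auto_report"),
      manual_review = sum(decisions$route == "manual_review"),
      discard = sum(decisions$route == "discard"),
      tier = as.list(table(decisions$final_tier)),
      prevalence_records = nrow(prevalence),
      n_samples = nrow(cohort$dosage)
    )
  )
  structure(
    list(filtered = filtered, filter_report = freport,
         decisions = decisions, prevalence = prevalence,
         class_table = class_table, gene_summary = gene_summary,
         group_totals = group_totals, carrier_fraction = carrier,
         regional = regional, migration = migration, manifest = manifest),
    class = "germtriage_run"
  )
}

#' @export
print.germtriage_run <- function(x, ...) {
  counts <- x$manifest$counts
  cat("germline triage run\n")
  cat("  variants in:   ", counts$variants_in, "\n")
  cat("  kept/dropped:  ", counts$kept, "/", counts$dropped, "\n")
  cat("  routes:        auto ", counts$auto_report, ", manual ",
      counts$manual_review, ", discard ", counts$discard, "\n", sep = "")
  tiers <- unlist(counts$tier)
  cat("  tiers:         ",
      paste(names(tiers), tiers, sep = "=", collapse = ", "), "\n")
  cat("  PV/LPV carrier fraction: ",
      format(x$carrier_fraction, digits = 3), "\n")
  invisible(x)
}

#' Tidy a triage run into its per-variant decision table
#'
#' @param x A `germtriage_run`.
#' @param ... Unused.
#' @return The decision tibble, one row per triaged variant.
#' @method tidy germtriage_run
#' @export
tidy.germtriage_run <- function(x, ...) x$decisions

#' One-row summary of a triage run
#'
#' @param x A `germtriage_run`.
#' @param ... Unused.
#' @return One-row tibble of headline counts and the carrier fraction.
#' @method glance germtriage_run
#' @export
glance.germtriage_run <- function(x, ...) {
  counts <- x$manifest$counts
  tiers <- unlist(counts$tier)
  tibble::tibble(
    variants_in = counts$variants_in,
    kept = counts$kept,
    dropped = counts$dropped,
    auto_report = counts$auto_report,
    manual_review = counts$manual_review,
    discard = counts$discard,
    n_pv = sum(tiers[names(tiers) == "PV"]),
    n_lpv = sum(tiers[names(tiers) == "LPV"]),
    n_del_vus = sum(tiers[names(tiers) == "del_VUS"]),
    carrier_fraction = x$carrier_fraction
  )
}

#' Write the report bundle of a pipeline run
#'
#' Emits the per-variant triage table, the filter report, the prevalence
#' table (with MAFs rounded to two significant figures alongside the
#' full-precision values), the functional-class matrix, the
#' constraint-stratified gene summary with group totals, the regional
#' summary, the migration matrix, and a JSON manifest.
#'
#' @param run A `germtriage_run`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_report_bundle <- function(run, out_dir) {
  stopifnot(inherits(run, "germtriage_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prev <- run$prevalence
  prev$maf_reported <- signif_maf(prev$maf)
  paths <- c(
    triage = file.path(out_dir, "triage.tsv"),
    filter_report = file.path(out_dir, "filter_report.tsv"),
    prevalence = file.path(out_dir, "prevalence.tsv"),
    class_table = file.path(out_dir, "functional_class_table.tsv"),
    gene_summary = file.path(out_dir, "gene_summary.tsv"),
    group_totals = file.path(out_dir, "constraint_group_totals.tsv"),
    regional = file.path(out_dir, "regional_summary.tsv"),
    migration = file.path(out_dir, "migration_matrix.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_tsv(run$decisions, paths[["triage"]], na = "")
  readr::write_tsv(run$filter_report, paths[["filter_report"]])
  readr::write_tsv(prev, paths[["prevalence"]], na = "")
  readr::write_tsv(run$class_table, paths[["class_table"]])
  readr::write_tsv(run$gene_summary, paths[["gene_summary"]])
  readr::write_tsv(run$group_totals, paths[["group_totals"]])
  readr::write_tsv(run$regional, paths[["regional"]])
  readr::write_tsv(tidy(run$migration), paths[["migration"]])
  jsonlite::write_json(run$manifest, paths[["manifest"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}
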