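#' Allele and carrier counts for one variant
#'
#' Tallies a diploid dosage vector: alternate-allele count, heterozygote
#' and homozygote counts, carriers, and the number of samples with a
#' non-missing genotype. Missing genotypes drop out of both numerator and
#' denominator.
#'
#' @param dosage Integer vector with values in `{0, 1, 2, NA}`.
#' @return One-row tibble: `ac`, `n_het`, `n_hom`, `n_called`, `carriers`.
#' @export
#' @examples
#' count_alleles(c(1, 1, 0, 2, NA))
count_alleles <- function(dosage) {
  if (!all(dosage %in% c(0L, 1L, 2L, NA))) {
    stop("dosage values must be 0, 1, 2, or NA", call. = FALSE)
  }
  called <- dosage[!is.na(dosage)]
  tibble::tibble(
    ac = as.integer(sum(called)),
    n_het = as.integer(sum(called == 1)),
    n_hom = as.integer(sum(called == 2)),
    n_called = length(called),
    carriers = as.integer(sum(called > 0))
  )
}

#' Minor allele frequency from allele counts
#'
#' MAF = `ac / (2 * n_called)` on diploid autosomes. Values are kept at
#' full precision; the reporting layer rounds to two significant figures
#' (see [signif_maf()]).
#'
#' @param ac Alternate-allele count(s).
#' @param n_called Number(s) of samples with called genotypes.
#' @return Numeric vector of frequencies in `[0, 1]`.
#' @export
#' @examples
#' compute_maf(113, 74996)
compute_maf <- function(ac, n_called) {
  if (any(n_called == 0)) stop("n_called must be positive", call. = FALSE)
  if (any(ac < 0) || any(ac > 2 * n_called)) {
    stop("ac must lie in [0, 2 * n_called]", call. = FALSE)
  }
  ac / (2 * n_called)
}

#' Round a frequency to reporting precision
#'
#' @param maf Numeric vector.
#' @param digits Significant figures (default 2, the reporting convention).
#' @return Rounded vector.
#' @export
signif_maf <- function(maf, digits = 2) signif(maf, digits)

#' Per-variant prevalence records
#'
#' Builds the per-variant allele-statistics table for triaged variants in
#' the reportable tiers (`PV`, `LPV`, `del_VUS`): allele counts,
#' zygosity, carriers, and cohort MAF, with the triage tier and
#' prevalence eligibility carried along.
#'
#' @param decisions Triage decision tibble from [triage_cohort()].
#' @param dosage Dosage matrix from [read_cohort_vcf()] /
#'   [simulate_genotypes()].
#' @param tiers Tiers to include (default `PV`, `LPV`, `del_VUS`).
#' @param eligible_only Keep only `prevalence_eligible` variants
#'   (default TRUE).
#' @return Tibble with one row per variant.
#' @export
prevalence_table <- function(decisions, dosage,
                             tiers = c("PV", "LPV", "del_VUS"),
                             eligible_only = TRUE) {
  rec <- decisions[decisions$final_tier %in% tiers, , drop = FALSE]
  if (eligible_only) rec <- rec[rec$prevalence_eligible, , drop = FALSE]
  missing_gt <- setdiff(rec$variant_id, colnames(dosage))
  if (length(missing_gt) > 0L) {
    stop("no genotypes for: ", paste(missing_gt, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(rec) == 0L) {
    return(tibble::tibble(
      variant_id = character(), gene = character(),
      final_tier = character(), novel = logical(),
      prevalence_eligible = logical(), ac = integer(), n_het = integer(),
      n_hom = integer(), n_called = integer(), carriers = integer(),
      maf = double()
    ))
  }
  counts <- purrr::map(rec$variant_id,
                       function(v) count_alleles(dosage[, v]))
  counts <- dplyr::bind_rows(counts)
  out <- dplyr::bind_cols(
    rec[, c("variant_id", "gene", "final_tier", "novel",
            "prevalence_eligible")],
    counts
  )
  out$maf <- ifelse(out$n_called > 0,
                    out$ac / (2 * out$n_called), NA_real_)
  out
}

#' Functional-class composition of the reported tiers
#'
#' Cross-tabulates distinct reported variants by functional class and
#' reporting group: PV/LPV registered in ClinVar, del-VUS registered in
#' ClinVar, and novel del-VUS ("registered" means any ClinVar submission,
#' i.e. status other than `not_submitted`). Novel variants can only be
#' del-VUS by construction of the triage tree.
#'
#' @param decisions Triage decision tibble.
#' @param annotations Annotation tibble (for `functional_class`).
#' @param classes Functional classes to report rows for (default the five
#'   reportable classes).
#' @return Tibble with `functional_class` rows and the three group-count
#'   columns; column sums equal the group sizes.
#' @export
functional_class_table <- function(decisions, annotations,
                                   classes = c(
                                     "nonsynonymous_SNV", "stop_gain",
                                     "frameshift_deletion",
                                     "frameshift_insertion", "splice_site"
                                   )) {
  ann <- annotations[match(decisions$variant_id, annotations$variant_id), ]
  d <- decisions
  d$functional_class <- ann$functional_class
  pvlpv <- d$final_tier %in% c("PV", "LPV") & !d$novel
  dv_reg <- d$final_tier == "del_VUS" & !d$novel
  dv_nov <- d$final_tier == "del_VUS" & d$novel
  tab <- function(sel) {
    as.integer(table(factor(d$functional_class[sel], levels = classes)))
  }
  tibble::tibble(
    functional_class = classes,
    pv_lpv_registered = tab(pvlpv),
    del_vus_registered = tab(dv_reg),
    del_vus_novel = tab(dv_nov)
  )
}

#' Per-gene allele totals over the reported tiers
#'
#' Sums alternate-allele counts of prevalence-eligible PV/LPV/del-VUS
#' records per gene.
#'
#' @param records Prevalence tibble from [prevalence_table()].
#' @return Tibble with `gene` and `total_alleles`.
#' @export
gene_allele_totals <- function(records) {
  records |>
    dplyr::filter(.data$prevalence_eligible,
                  .data$final_tier %in% c("PV", "LPV", "del_VUS")) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(total_alleles = sum(.data$ac), .groups = "drop")
}

#' Constraint-stratified gene summary
#'
#' Joins per-gene allele totals to pLI/LOEUF constraint metrics and
#' assigns the conservation class: a gene is `conserved` when its LOEUF is
#' below 0.35 (strong selection against loss of function), else
#' `nonconserved`. The split follows the LOEUF ranking alone; pLI is
#' carried for reference.
#'
#' @param gene_totals Tibble with `gene` and `total_alleles` (from
#'   [gene_allele_totals()] or transcribed published totals).
#' @param constraint_table Tibble with `gene`, `pli`, `loeuf`
#'   (default [default_constraint_table()]).
#' @param loeuf_threshold Conservation cut (default 0.35).
#' @return `gene_totals` with `pli`, `loeuf`, `conservation` added, sorted
#'   by LOEUF.
#' @export
gene_constraint_summary <- function(gene_totals,
                                    constraint_table =
                                      default_constraint_table(),
                                    loeuf_threshold = 0.35) {
  unknown <- setdiff(gene_totals$gene, constraint_table$gene)
  if (length(unknown) > 0L) {
    stop("no constraint metrics for gene(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  gene_totals |>
    dplyr::inner_join(constraint_table, by = "gene") |>
    dplyr::mutate(conservation = ifelse(.data$loeuf < loeuf_threshold,
                                        "conserved", "nonconserved")) |>
    dplyr::arrange(.data$loeuf)
}

#' Allele totals per conservation group
#'
#' @param gene_summary Output of [gene_constraint_summary()].
#' @return Tibble with `conservation` and `total_alleles` (both groups
#'   always present).
#' @export
constraint_group_totals <- function(gene_summary) {
  gene_summary |>
    dplyr::mutate(conservation = factor(.data$conservation,
                                        levels = c("conserved",
                                                   "nonconserved"))) |>
    dplyr::group_by(.data$conservation, .drop = FALSE) |>
    dplyr::summarise(total_alleles = sum(.data$total_alleles, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(conservation = as.character(.data$conservation))
}

# sample ids carrying at least one qualifying variant
.carrier_samples <- function(decisions, dosage, tiers) {
  ids <- decisions$variant_id[
    decisions$final_tier %in% tiers & decisions$prevalence_eligible]
  ids <- intersect(ids, colnames(dosage))
  if (length(ids) == 0L) return(character(0))
  sub <- dosage[, ids, drop = FALSE]
  hit <- rowSums(sub > 0, na.rm = TRUE) > 0
  rownames(sub)[hit]
}

#' Fraction of samples carrying a qualifying variant
#'
#' Counts distinct samples with at least one alternate allele across the
#' given tiers; a sample carrying several qualifying variants counts once.
#'
#' @param decisions Triage decision tibble.
#' @param dosage Dosage matrix.
#' @param tiers Qualifying tiers (default `PV`, `LPV`).
#' @return Single numeric fraction of all samples in `dosage`.
#' @export
carrier_fraction <- function(decisions, dosage, tiers = c("PV", "LPV")) {
  length(.carrier_samples(decisions, dosage, tiers)) / nrow(dosage)
}

#' Variants shared between two cohorts
#'
#' Intersects two cohorts' reported variant sets by exact variant key and
#' reports the per-cohort MAF pair for each shared variant.
#'
#' @param records_a,records_b Prevalence tibbles from [prevalence_table()].
#' @param suffixes Column suffixes for the two cohorts.
#' @return Tibble with one row per shared key.
#' @export
compare_cohorts <- function(records_a, records_b,
                            suffixes = c("_g1", "_g2")) {
  keep <- c("variant_id", "gene", "final_tier", "ac", "maf")
  dplyr::inner_join(
    records_a[, keep], records_b[, keep],
    by = c("variant_id", "gene"), suffix = suffixes
  )
}
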