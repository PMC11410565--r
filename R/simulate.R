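# GRCh38 contigs and rough gene start coordinates used to fabricate
# plausible positions for synthetic variants (panel genes only)
.gene_loci <- function() {
  tibble::tribble(
    ~gene, ~chrom, ~base_pos,
    "APC", "5", 112707498L, "BMPR1A", "10", 86755786L,
    "BRCA1", "17", 43044295L, "BRCA2", "13", 32315508L,
    "MAX", "14", 65006102L, "MEN1", "11", 64803513L,
    "MLH1", "3", 36993350L, "MSH2", "2", 47403067L,
    "MSH6", "2", 47783145L, "MUTYH", "1", 45329163L,
    "NF2", "22", 29603832L, "PALB2", "16", 23603160L,
    "PMS2", "7", 5970925L, "PTEN", "10", 87863113L,
    "RB1", "13", 48303748L, "RET", "10", 43077027L,
    "SDHAF2", "11", 61430172L, "SDHB", "1", 17018722L,
    "SDHC", "1", 161314257L, "SDHD", "11", 112086873L,
    "SMAD4", "18", 51028394L, "STK11", "19", 1205778L,
    "TMEM127", "2", 96246606L, "TP53", "17", 7668402L,
    "TSC1", "9", 132891349L, "TSC2", "16", 2047982L,
    "VHL", "3", 10141778L, "WT1", "11", 32387775L
  )
}

.sim_regions <- function() {
  c("Moscow", "Central", "Northwest", "Volga", "South", "Caucasus",
    "Urals", "Siberia", "Far_East")
}

#' Simulation settings for a synthetic cohort
#'
#' Defines the statistical structure of a generated cohort: rare true MAFs
#' drawn log-uniformly, a mixture of planted triage categories whose
#' evidence is constructed to land on a known route and final tier,
#' contaminant decoys for each filtration reason, per-predictor hit
#' probability for planted deleterious scores, and categorical laws for
#' the sample metadata.
#'
#' Planted categories: `auto_pv`/`auto_lpv` (ClinVar P or LP at high
#' review status with engine-pathogenic criteria), `confirmed_plp`
#' (single-submitter P/LP with literature support), `downgraded_plp`
#' (same without literature), `vus_delvus` (ClinVar-unsettled,
#' engine-pathogenic), `novel_delvus` (never submitted,
#' engine-pathogenic), `benign_vus` (no pathogenic signal; discarded).
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param n_samples Number of diploid samples (default 2000).
#' @param n_variants Number of variants including decoys (default 300).
#' @param cohort_label `"group1"` or `"group2"`.
#' @param maf_range True-MAF range for the log-uniform law
#'   (default `[1e-5, 5e-3]`).
#' @param category_mixture Named probabilities over planted categories.
#' @param class_mixture Named probabilities over the five reportable
#'   functional classes.
#' @param contaminant_fracs Named fractions (of `n_variants`) of
#'   `synonymous`, `common` (gnomAD AF > 5%), and `benign` (ClinVar B/LB)
#'   decoys.
#' @param p_hit Probability that each planted-deleterious predictor score
#'   falls on the deleterious side of its threshold (default 0.9,
#'   independently per predictor).
#' @param region_probs Named probabilities over regions for birth region.
#' @param stay_prob Probability a sample resides where born (default 0.85).
#' @param missing_region_frac Fraction of samples with unknown regions.
#' @param missing_gt_frac Per-genotype missingness rate.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 2000L,
                       n_variants = 300L,
                       cohort_label = c("group1", "group2"),
                       maf_range = c(1e-5, 5e-3),
                       category_mixture = c(
                         auto_pv = 0.15, auto_lpv = 0.05,
                         confirmed_plp = 0.15, downgraded_plp = 0.10,
                         vus_delvus = 0.15, novel_delvus = 0.25,
                         benign_vus = 0.15
                       ),
                       class_mixture = c(
                         nonsynonymous_SNV = 0.25, stop_gain = 0.30,
                         frameshift_deletion = 0.20,
                         frameshift_insertion = 0.12, splice_site = 0.13
                       ),
                       contaminant_fracs = c(
                         synonymous = 0.08, common = 0.05, benign = 0.07
                       ),
                       p_hit = 0.9,
                       region_probs = NULL,
                       stay_prob = 0.85,
                       missing_region_frac = 0.1,
                       missing_gt_frac = 0.002) {
  cohort_label <- match.arg(cohort_label)
  if (is.null(region_probs)) {
    region_probs <- stats::setNames(
      c(0.30, 0.15, 0.10, 0.12, 0.08, 0.05, 0.08, 0.08, 0.04),
      .sim_regions()
    )
  }
  stopifnot(n_samples > 0L, n_variants > 0L,
            maf_range[1] > 0, maf_range[2] <= 0.05,
            p_hit >= 0, p_hit <= 1,
            sum(contaminant_fracs) < 1)
  for (p in list(category_mixture, class_mixture, region_probs)) {
    if (abs(sum(p) - 1) > 1e-8) {
      stop("probability vectors must sum to 1", call. = FALSE)
    }
  }
  structure(
    list(seed = as.integer(seed), n_samples = as.integer(n_samples),
         n_variants = as.integer(n_variants), cohort_label = cohort_label,
         maf_range = maf_range, category_mixture = category_mixture,
         class_mixture = class_mixture,
         contaminant_fracs = contaminant_fracs, p_hit = p_hit,
         region_probs = region_probs, stay_prob = stay_prob,
         missing_region_frac = missing_region_frac,
         missing_gt_frac = missing_gt_frac),
    class = "sim_config"
  )
}

# draw a predictor score uniformly on the deleterious or benign side of
# its published threshold
.draw_score <- function(predictor, deleterious) {
  n <- length(deleterious)
  lo_hi <- switch(predictor,
    sift = list(del = c(0, 0.05), ben = c(0.05, 1)),
    polyphen2_hdiv = list(del = c(0.95, 1), ben = c(0, 0.95)),
    mutation_assessor = list(del = c(2, 4), ben = c(-2, 2)),
    mcap = list(del = c(0.025, 1), ben = c(0, 0.025)),
    cadd = list(del = c(15, 40), ben = c(0, 15)),
    revel = list(del = c(0.75, 1), ben = c(0, 0.75)),
    metalr = list(del = c(0.5, 1), ben = c(0, 0.5))
  )
  out <- numeric(n)
  out[deleterious] <- stats::runif(sum(deleterious),
                                   lo_hi$del[1], lo_hi$del[2])
  out[!deleterious] <- stats::runif(sum(!deleterious),
                                    lo_hi$ben[1], lo_hi$ben[2])
  out
}

.random_alleles <- function(class) {
  bases <- c("A", "C", "G", "T")
  n <- length(class)
  ref <- character(n)
  alt <- character(n)
  for (i in seq_len(n)) {
    anchor <- sample(bases, 1)
    if (class[i] == "frameshift_deletion") {
      extra <- paste(sample(bases, sample(1:3, 1), replace = TRUE),
                     collapse = "")
      ref[i] <- paste0(anchor, extra)
      alt[i] <- anchor
    } else if (class[i] == "frameshift_insertion") {
      extra <- paste(sample(bases, sample(1:3, 1), replace = TRUE),
                     collapse = "")
      ref[i] <- anchor
      alt[i] <- paste0(anchor, extra)
    } else {
      ref[i] <- anchor
      alt[i] <- sample(setdiff(bases, anchor), 1)
    }
  }
  list(ref = ref, alt = alt)
}

#' Generate annotated synthetic variant sites with truth labels
#'
#' Draws variant sites according to a [sim_config()]: each kept variant is
#' planted into a triage category with ClinVar class/status, ACMG
#' criterion flags satisfying (or not) a combining rule, predictor scores
#' drawn on the deleterious or benign side of each published threshold
#' with probability `p_hit` per predictor, and a literature-support flag.
#' Decoy variants are inserted for each filtration reason. The truth
#' table records, per variant, the planted category, the true MAF, and
#' the expected filter reason, route, and final tier derived from the
#' planted evidence by generator-side bookkeeping (independent of the
#' pipeline's own routing code).
#'
#' @param config A [sim_config()].
#' @return List with `annotations` (tibble in the annotation-table schema
#'   plus `variant_id`) and `truth` (tibble keyed by `variant_id`).
#' @export
generate_sites <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .generate_sites_impl(config))
}

.generate_sites_impl <- function(config) {
  n <- config$n_variants
  n_syn <- round(config$contaminant_fracs[["synonymous"]] * n)
  n_common <- round(config$contaminant_fracs[["common"]] * n)
  n_benign <- round(config$contaminant_fracs[["benign"]] * n)
  n_kept <- n - n_syn - n_common - n_benign
  category <- c(
    sample(names(config$category_mixture), n_kept, replace = TRUE,
           prob = config$category_mixture),
    rep("decoy_synonymous", n_syn),
    rep("decoy_common", n_common),
    rep("decoy_benign", n_benign)
  )
  loci <- .gene_loci()
  gene_idx <- sample.int(nrow(loci), n, replace = TRUE)
  gene <- loci$gene[gene_idx]
  chrom <- loci$chrom[gene_idx]
  pos <- loci$base_pos[gene_idx] + sample.int(500000L, n, replace = FALSE)
  fclass <- sample(names(config$class_mixture), n, replace = TRUE,
                   prob = config$class_mixture)
  fclass[category == "decoy_synonymous"] <- "synonymous"
  fclass[category == "decoy_common"] <- "nonsynonymous_SNV"
  fclass[category == "decoy_benign"] <- "nonsynonymous_SNV"
  alleles <- .random_alleles(fclass)
  true_maf <- exp(stats::runif(n, log(config$maf_range[1]),
                               log(config$maf_range[2])))
  gnomad_af <- true_maf * exp(stats::rnorm(n, 0, 0.2))
  gnomad_af[category == "decoy_common"] <-
    stats::runif(n_common, 0.06, 0.5)
  # a sampled subset of rare variants is absent from gnomAD entirely
  absent <- category != "decoy_common" & stats::runif(n) < 0.15
  gnomad_af[absent] <- NA_real_

  pathogenic_planted <- category %in% c(
    "auto_pv", "auto_lpv", "confirmed_plp", "downgraded_plp",
    "vus_delvus", "novel_delvus"
  )
  clinvar_class <- character(n)
  clinvar_status <- character(n)
  acmg_flags <- character(n)
  literature <- logical(n)
  high <- c("expert_panel", "multiple_submitters")
  low <- c("single_submitter", "no_assertion")
  for (i in seq_len(n)) {
    switch(category[i],
      auto_pv = {
        clinvar_class[i] <- "P"
        clinvar_status[i] <- sample(high, 1)
        acmg_flags[i] <- "PVS1;PS3;PM2"
        literature[i] <- TRUE
      },
      auto_lpv = {
        clinvar_class[i] <- "LP"
        clinvar_status[i] <- sample(high, 1)
        acmg_flags[i] <- "PVS1;PM2"
        literature[i] <- TRUE
      },
      confirmed_plp = {
        clinvar_class[i] <- sample(c("P", "LP", "P_LP"), 1)
        clinvar_status[i] <- sample(low, 1)
        acmg_flags[i] <- "PVS1;PS3"
        literature[i] <- TRUE
      },
      downgraded_plp = {
        clinvar_class[i] <- sample(c("P", "LP"), 1)
        clinvar_status[i] <- sample(low, 1)
        acmg_flags[i] <- "PVS1;PS3"
        literature[i] <- FALSE
      },
      vus_delvus = {
        clinvar_class[i] <- sample(c("VUS", "conflicting", "not_provided"), 1)
        clinvar_status[i] <- sample(low, 1)
        acmg_flags[i] <- "PVS1;PS3"
        literature[i] <- FALSE
      },
      novel_delvus = {
        clinvar_class[i] <- "not_submitted"
        clinvar_status[i] <- "not_submitted"
        acmg_flags[i] <- "PVS1;PM2"
        literature[i] <- FALSE
      },
      benign_vus = {
        clinvar_class[i] <- "VUS"
        clinvar_status[i] <- sample(low, 1)
        acmg_flags[i] <- "PM2;PP3"
        literature[i] <- FALSE
      },
      decoy_synonymous = {
        clinvar_class[i] <- "VUS"
        clinvar_status[i] <- "single_submitter"
        acmg_flags[i] <- "BP7"
        literature[i] <- FALSE
      },
      decoy_common = {
        clinvar_class[i] <- "VUS"
        clinvar_status[i] <- "single_submitter"
        acmg_flags[i] <- "BS1"
        literature[i] <- FALSE
      },
      decoy_benign = {
        clinvar_class[i] <- sample(c("B", "LB"), 1)
        clinvar_status[i] <- "multiple_submitters"
        acmg_flags[i] <- "BA1;BP4"
        literature[i] <- FALSE
      }
    )
  }

  # predictor scores: deleterious-planted variants hit each threshold
  # independently with probability p_hit, benign-planted with 1 - p_hit
  p_del <- ifelse(pathogenic_planted, config$p_hit, 1 - config$p_hit)
  primary <- c("sift", "polyphen2_hdiv", "mutation_assessor", "mcap", "cadd")
  hits <- matrix(stats::runif(n * 7) < rep(p_del, 7), nrow = n)
  colnames(hits) <- c(primary, "revel", "metalr")
  scores <- lapply(colnames(hits), function(pr) .draw_score(pr, hits[, pr]))
  names(scores) <- colnames(hits)

  votes <- rowSums(hits[, primary, drop = FALSE])
  resolver <- hits[, "revel"] & hits[, "metalr"]
  expected_verdict <- dplyr::case_when(
    votes >= 3 ~ "supported",
    votes == 0 ~ "not_supported",
    resolver ~ "conflicting_resolved_supported",
    TRUE ~ "conflicting_resolved_not_supported"
  )
  supported <- expected_verdict %in%
    c("supported", "conflicting_resolved_supported")

  expected_filter_reason <- dplyr::case_when(
    category == "decoy_synonymous" ~ "disallowed_class",
    category == "decoy_common" ~ "af_above_max",
    category == "decoy_benign" ~ "clinvar_benign",
    TRUE ~ NA_character_
  )
  expected_route <- dplyr::case_when(
    !is.na(expected_filter_reason) ~ NA_character_,
    category %in% c("auto_pv", "auto_lpv") ~ "auto_report",
    category == "benign_vus" ~ "discard",
    TRUE ~ "manual_review"
  )
  expected_tier <- dplyr::case_when(
    !is.na(expected_filter_reason) ~ NA_character_,
    category == "auto_pv" ~ "PV",
    category == "auto_lpv" ~ "LPV",
    category == "novel_delvus" ~ "del_VUS",
    category == "confirmed_plp" & supported &
      clinvar_class == "P" ~ "PV",
    category == "confirmed_plp" & supported ~ "LPV",
    category == "downgraded_plp" & supported ~ "del_VUS",
    category == "vus_delvus" & supported ~ "del_VUS",
    category == "benign_vus" ~ "excluded",
    TRUE ~ "excluded"
  )

  rsid <- ifelse(clinvar_status == "not_submitted", NA_character_,
                 paste0("rsSIM", seq_len(n)))
  hgvs_g <- paste0("NC_sim.", chrom, ":g.", pos, alleles$ref, ">",
                   alleles$alt)
  annotations <- tibble::tibble(
    chrom = chrom, pos = pos, ref = alleles$ref, alt = alleles$alt,
    gene = gene, functional_class = fclass, hgvs_g = hgvs_g, rsid = rsid,
    gnomad_af = gnomad_af, clinvar_class = clinvar_class,
    clinvar_status = clinvar_status,
    sift = scores$sift, polyphen2_hdiv = scores$polyphen2_hdiv,
    mutation_assessor = scores$mutation_assessor, mcap = scores$mcap,
    cadd = scores$cadd, revel = scores$revel, metalr = scores$metalr,
    acmg_flags = acmg_flags,
    gof_lof = "unknown",
    literature_support = literature
  )
  annotations <- normalize_variants(annotations)
  annotations <- dplyr::relocate(annotations, "variant_id")
  truth <- tibble::tibble(
    variant_id = annotations$variant_id,
    category = category,
    planted_pathogenic = pathogenic_planted,
    true_maf = true_maf,
    expected_verdict = expected_verdict,
    expected_filter_reason = expected_filter_reason,
    expected_route = expected_route,
    expected_tier = expected_tier
  )
  list(annotations = annotations, truth = truth)
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Each sample's dosage at each variant is an independent
#' Binomial(2, maf) draw (random mating, no relatedness, no linkage).
#'
#' @param true_mafs Numeric vector of true allele frequencies, optionally
#'   named by `variant_id`.
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @param missing_gt_frac Per-genotype missingness rate (default 0).
#' @return Integer matrix (samples x variants) with entries in
#'   `{0, 1, 2, NA}`; row names are sample ids.
#' @export
simulate_genotypes <- function(true_mafs, n_samples, seed,
                               missing_gt_frac = 0) {
  stopifnot(all(true_mafs >= 0), all(true_mafs <= 1))
  withr::with_seed(as.integer(seed), {
    m <- length(true_mafs)
    dosage <- matrix(
      stats::rbinom(n_samples * m, 2L, rep(true_mafs, each = n_samples)),
      nrow = n_samples, ncol = m
    )
    if (missing_gt_frac > 0) {
      dosage[stats::runif(length(dosage)) < missing_gt_frac] <- NA_integer_
    }
    rownames(dosage) <- sprintf("S%05d", seq_len(n_samples))
    colnames(dosage) <- names(true_mafs)
    dosage
  })
}

.simulate_samples <- function(config) {
  n <- config$n_samples
  regions <- names(config$region_probs)
  birth <- sample(regions, n, replace = TRUE, prob = config$region_probs)
  stay <- stats::runif(n) < config$stay_prob
  residence <- birth
  movers <- which(!stay)
  for (i in movers) {
    residence[i] <- sample(setdiff(regions, birth[i]), 1)
  }
  unknown <- stats::runif(n) < config$missing_region_frac
  birth[unknown] <- NA_character_
  residence[unknown] <- NA_character_
  age_range <- if (config$cohort_label == "group1") c(17, 90) else c(90, 104)
  tibble::tibble(
    sample_id = sprintf("S%05d", seq_len(n)),
    cohort = config$cohort_label,
    age = round(stats::runif(n, age_range[1], age_range[2])),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.55, 0.45)),
    birth_region = birth,
    residence_region = residence
  )
}

#' Simulate a complete synthetic cohort
#'
#' Generates annotated sites with truth labels, Hardy-Weinberg genotypes
#' at the planted true MAFs, and sample metadata with regional structure.
#' Fully reproducible: the same config (including seed) yields identical
#' output.
#'
#' @param config A [sim_config()].
#' @return Object of class `germtriage_cohort`: list with `config`,
#'   `annotations`, `truth`, `dosage`, `samples`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  sites <- generate_sites(config)
  mafs <- stats::setNames(sites$truth$true_maf, sites$truth$variant_id)
  dosage <- simulate_genotypes(mafs, config$n_samples,
                               seed = config$seed + 1L,
                               missing_gt_frac = config$missing_gt_frac)
  samples <- withr::with_seed(config$seed + 2L, .simulate_samples(config))
  structure(
    list(config = config, annotations = sites$annotations,
         truth = sites$truth, dosage = dosage, samples = samples),
    class = "germtriage_cohort"
  )
}

#' Write a synthetic cohort to disk
#'
#' Emits `cohort.vcf`, `annotations.tsv`, `samples.tsv`, and `truth.tsv`
#' into a directory. Output is deterministic: the same cohort written
#' twice gives byte-identical files. The VCF and annotation table
#' round-trip exactly through [read_cohort_vcf()] and
#' [read_annotation_table()].
#'
#' @param cohort A `germtriage_cohort` from [simulate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "germtriage_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(out_dir, "cohort.vcf"),
    annotations = file.path(out_dir, "annotations.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_cohort_vcf(cohort$annotations, cohort$dosage, paths[["vcf"]])
  write_annotation_table(cohort$annotations, paths[["annotations"]])
  readr::write_tsv(cohort$samples, paths[["samples"]], na = "")
  readr::write_tsv(cohort$truth, paths[["truth"]], na = "NA")
  invisible(paths)
}
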