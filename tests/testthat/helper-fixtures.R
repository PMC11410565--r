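# one-row (or n-row) annotation tibble with sensible defaults, overridable
# field by field
make_ann <- function(n = 1, chrom = "13", pos = 32340000 + seq_len(n),
                     ref = "C", alt = "T", gene = "BRCA2",
                     functional_class = "nonsynonymous_SNV",
                     hgvs_g = NA_character_, rsid = NA_character_,
                     gnomad_af = NA_real_, clinvar_class = "VUS",
                     clinvar_status = "single_submitter",
                     sift = NA_real_, polyphen2_hdiv = NA_real_,
                     mutation_assessor = NA_real_, mcap = NA_real_,
                     cadd = NA_real_, revel = NA_real_, metalr = NA_real_,
                     acmg_flags = NA_character_, gof_lof = "unknown",
                     literature_support = FALSE) {
  ann <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt, gene = gene,
    functional_class = functional_class, hgvs_g = hgvs_g, rsid = rsid,
    gnomad_af = gnomad_af, clinvar_class = clinvar_class,
    clinvar_status = clinvar_status, sift = sift,
    polyphen2_hdiv = polyphen2_hdiv, mutation_assessor = mutation_assessor,
    mcap = mcap, cadd = cadd, revel = revel, metalr = metalr,
    acmg_flags = acmg_flags, gof_lof = gof_lof,
    literature_support = literature_support
  )
  ann$variant_id <- variant_id(ann$chrom, ann$pos, ann$ref, ann$alt)
  dplyr::relocate(ann, "variant_id")
}

# deleterious-side predictor scores (all seven)
deleterious_scores <- function(ann) {
  ann$sift <- 0.01
  ann$polyphen2_hdiv <- 0.99
  ann$mutation_assessor <- 3
  ann$mcap <- 0.2
  ann$cadd <- 28
  ann$revel <- 0.9
  ann$metalr <- 0.8
  ann
}

# write a VCF from raw lines (header included)
write_vcf_lines <- function(body, samples = c("S1", "S2", "S3")) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  path
}

small_sim <- function(seed = 11, n_samples = 150, n_variants = 80, ...) {
  simulate_cohort(sim_config(seed = seed, n_samples = n_samples,
                             n_variants = n_variants, ...))
}
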