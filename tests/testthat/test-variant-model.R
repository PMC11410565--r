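test_that("normalization trims shared bases and keeps minimal SNVs intact", {
  out <- normalize_variants(
    data.frame(chrom = "1", pos = 100, ref = "CAG", alt = "CG")
  )
  expect_equal(out$pos, 100L)
  expect_equal(out$ref, "CA")
  expect_equal(out$alt, "C")

  snv <- normalize_variants(
    data.frame(chrom = "1", pos = 100, ref = "C", alt = "T")
  )
  expect_equal(snv$pos, 100L)
  expect_equal(snv$ref, "C")
  expect_equal(snv$alt, "T")
})

test_that("all padded spellings of one indel map to one canonical key", {
  # canonical deletion: pos 500, AT > A
  canonical <- normalize_variants(
    data.frame(chrom = "2", pos = 500, ref = "AT", alt = "A")
  )
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (i in 1:25) {
    lead <- paste(sample(bases, sample(0:3, 1), replace = TRUE),
                  collapse = "")
    trail <- paste(sample(bases, sample(0:3, 1), replace = TRUE),
                   collapse = "")
    padded <- data.frame(
      chrom = "2", pos = 500 - nchar(lead),
      ref = paste0(lead, "AT", trail),
      alt = paste0(lead, "A", trail)
    )
    out <- normalize_variants(padded)
    expect_equal(out$variant_id, canonical$variant_id)
  }
})

test_that("normalization is idempotent", {
  set.seed(7)
  vars <- data.frame(
    chrom = "5", pos = sample(1000:2000, 20),
    ref = replicate(20, paste(sample(c("A", "C", "G", "T"),
                                     sample(1:4, 1), replace = TRUE),
                              collapse = "")),
    alt = replicate(20, paste(sample(c("A", "C", "G", "T"),
                                     sample(1:4, 1), replace = TRUE),
                              collapse = ""))
  )
  vars <- vars[vars$ref != vars$alt, ]
  once <- normalize_variants(vars)
  twice <- normalize_variants(once)
  expect_equal(twice$variant_id, once$variant_id)
})

test_that("degenerate keys are rejected", {
  expect_error(
    normalize_variants(data.frame(chrom = "1", pos = 5, ref = "A",
                                  alt = "A")),
    "must differ"
  )
  expect_error(
    normalize_variants(data.frame(chrom = "1", pos = 0, ref = "A",
                                  alt = "T")),
    "pos"
  )
  expect_error(
    normalize_variants(data.frame(chrom = "1", pos = 5, ref = "A",
                                  alt = "N")),
    "A,C,G,T"
  )
  long_ref <- paste(rep("A", 60), collapse = "")
  expect_error(
    normalize_variants(data.frame(chrom = "1", pos = 5,
                                  ref = paste0(long_ref, "C"), alt = "T")),
    "50 bp"
  )
})

test_that("GT fields translate to dosages and multi-allelics decompose", {
  path <- write_vcf_lines(paste(
    c("1", "45331556", ".", "C", "T", ".", "PASS", ".", "GT",
      "0/1", "1/1", "0/0"), collapse = "\t"))
  out <- read_cohort_vcf(path)
  expect_equal(out$variants$variant_id, "1:45331556:C:T")
  expect_equal(unname(out$dosage[, 1]), c(1L, 2L, 0L))

  path2 <- write_vcf_lines(paste(
    c("7", "6002670", ".", "C", "T,G", ".", "PASS", ".", "GT",
      "0/1", "1/2", "2/2"), collapse = "\t"))
  out2 <- read_cohort_vcf(path2)
  expect_equal(nrow(out2$variants), 2L)
  expect_equal(unique(out2$variants$chrom), "7")
  expect_equal(unique(out2$variants$ref), "C")
  expect_equal(unname(out2$dosage[, "7:6002670:C:T"]), c(1L, 1L, 0L))
  expect_equal(unname(out2$dosage[, "7:6002670:C:G"]), c(0L, 1L, 2L))
  # allele conservation: per-sample sum of per-alt dosages <= ploidy
  expect_true(all(rowSums(out2$dosage) <= 2))
})

test_that("missing and non-diploid genotypes are handled per contract", {
  path <- write_vcf_lines(paste(
    c("1", "100", ".", "A", "G", ".", "PASS", ".", "GT",
      "./.", "0/1", "0|1"), collapse = "\t"))
  out <- read_cohort_vcf(path)
  expect_equal(unname(out$dosage[, 1]), c(NA_integer_, 1L, 1L))

  bad <- write_vcf_lines(paste(
    c("1", "100", ".", "A", "G", ".", "PASS", ".", "GT",
      "0/1/1", "0/1", "0/0"), collapse = "\t"))
  expect_error(read_cohort_vcf(bad), "non-diploid")
  expect_error(read_cohort_vcf("no/such/file.vcf"), "not found")
})

test_that("synthetic cohort round-trips through the VCF writer and reader", {
  co <- small_sim()
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  back <- read_cohort_vcf(paths[["vcf"]])
  expect_equal(back$variants$variant_id, co$annotations$variant_id)
  expect_equal(unname(back$dosage), unname(co$dosage))
  ann_back <- read_annotation_table(paths[["annotations"]])
  expect_equal(ann_back$variant_id, co$annotations$variant_id)
  expect_equal(ann_back$gnomad_af, co$annotations$gnomad_af)
  expect_equal(ann_back$acmg_flags, co$annotations$acmg_flags)
  expect_equal(ann_back$literature_support,
               co$annotations$literature_support)
})

test_that("annotation reader enforces missingness, panel, and enums", {
  ann <- deleterious_scores(make_ann())
  ann$sift <- NA_real_
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(ann, path)
  back <- read_annotation_table(path)
  expect_true(is.na(back$sift))         # empty cell -> missing, not zero
  expect_equal(back$polyphen2_hdiv, 0.99)

  off <- make_ann(gene = "ATM")
  write_annotation_table(off, path)
  expect_error(read_annotation_table(path), "ATM")

  bad_enum <- make_ann(clinvar_class = "pathogenicish")
  write_annotation_table(bad_enum, path)
  expect_error(read_annotation_table(path), "allowed")

  dup <- dplyr::bind_rows(make_ann(), make_ann())
  write_annotation_table(dup, path)
  expect_error(read_annotation_table(path), "duplicate")

  mismatch <- make_ann(clinvar_class = "not_submitted",
                       clinvar_status = "single_submitter")
  write_annotation_table(mismatch, path)
  expect_error(read_annotation_table(path), "disagree")
})

test_that("a transcribed reference-table row reads back faithfully", {
  row <- make_ann(chrom = "1", pos = 45332803, ref = "T", alt = "C",
                  gene = "MUTYH", rsid = "rs34612342",
                  gnomad_af = 0.0015, clinvar_class = "LP",
                  clinvar_status = "multiple_submitters",
                  hgvs_g = "NC_000001.11:g.45332803T>C")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(row, path)
  back <- read_annotation_table(path)
  expect_equal(back$clinvar_class, "LP")
  expect_equal(back$gnomad_af, 0.0015)
  expect_equal(back$variant_id, "1:45332803:T:C")
})
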