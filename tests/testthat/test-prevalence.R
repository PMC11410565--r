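test_that("allele tallies honour their invariants", {
  out <- count_alleles(c(1, 1, 0))
  expect_equal(out$ac, 2L)
  expect_equal(out$n_het, 2L)
  expect_equal(out$n_hom, 0L)
  expect_equal(out$carriers, 2L)

  out <- count_alleles(c(2, 1, NA))
  expect_equal(out$ac, 3L)
  expect_equal(out$n_het, 1L)
  expect_equal(out$n_hom, 1L)
  expect_equal(out$n_called, 2L)
  expect_equal(out$carriers, 2L)

  expect_error(count_alleles(c(0, 3)), "dosage")

  # brute-force element-wise tally oracle on random vectors
  set.seed(31)
  for (i in 1:30) {
    dos <- sample(c(0L, 1L, 2L, NA), 50, replace = TRUE)
    got <- count_alleles(dos)
    ac <- 0L; het <- 0L; hom <- 0L; called <- 0L
    for (d in dos) {
      if (is.na(d)) next
      called <- called + 1L
      ac <- ac + d
      if (d == 1L) het <- het + 1L
      if (d == 2L) hom <- hom + 1L
    }
    expect_equal(got$ac, ac)
    expect_equal(got$n_het, het)
    expect_equal(got$n_hom, hom)
    expect_equal(got$n_called, called)
    expect_equal(got$ac, got$n_het + 2L * got$n_hom)
    expect_equal(got$carriers, got$n_het + got$n_hom)
  }
})

test_that("MAF arithmetic matches the printed reference rows", {
  expect_equal(signif_maf(compute_maf(113, 74996)), 0.00075)
  expect_equal(compute_maf(0, 74996), 0)
  expect_equal(compute_maf(2 * 74996, 74996), 1)
  expect_error(compute_maf(1, 0), "positive")
  expect_error(compute_maf(5, 2), "ac must lie")

  ref <- readr::read_tsv(
    system.file("extdata", "cohort_maf_reference.tsv",
                package = "germtriage"),
    show_col_types = FALSE
  )
  # the four rows whose printed counts are internally consistent
  rows <- ref[ref$rsid %in% c("rs34612342", "rs140342925", "rs1346312258",
                              "rs180177102"), ]
  expect_equal(nrow(rows), 4L)
  expect_equal(signif_maf(compute_maf(rows$ac, 74996)), rows$maf_printed)
})

test_that("MAF estimates recover simulated truth within binomial error", {
  m <- 0.01
  n <- 2000
  bound <- 3 * sqrt(m * (1 - m) / (2 * n)) + 1e-12
  inside <- vapply(1:1000, function(r) {
    dos <- simulate_genotypes(c(v = m), n, seed = 40000 + r)
    rec <- count_alleles(dos[, 1])
    est <- compute_maf(rec$ac, rec$n_called)
    abs(est - m) <= bound
  }, logical(1))
  expect_gte(mean(inside), 0.99)
})

test_that("functional-class tables reproduce planted mixtures", {
  empty <- functional_class_table(
    tibble::tibble(variant_id = character(), final_tier = character(),
                   novel = logical()),
    make_ann()[0, ]
  )
  expect_true(all(empty$pv_lpv_registered == 0))
  expect_true(all(empty$del_vus_registered == 0))
  expect_true(all(empty$del_vus_novel == 0))

  co <- small_sim(seed = 19, n_variants = 200)
  decisions <- triage_cohort(apply_filters(co$annotations))
  tab <- functional_class_table(decisions, co$annotations)
  truth <- dplyr::inner_join(
    co$truth, co$annotations[, c("variant_id", "functional_class")],
    by = "variant_id"
  )
  planted_novel <- truth[!is.na(truth$expected_tier) &
                           truth$expected_tier == "del_VUS" &
                           truth$category == "novel_delvus", ]
  expect_equal(sum(tab$del_vus_novel), nrow(planted_novel))
  planted_pvlpv <- truth[!is.na(truth$expected_tier) &
                           truth$expected_tier %in% c("PV", "LPV"), ]
  expect_equal(sum(tab$pv_lpv_registered), nrow(planted_pvlpv))
  expect_equal(as.integer(table(factor(planted_novel$functional_class,
                                       levels = tab$functional_class))),
               tab$del_vus_novel)
})

test_that("constraint stratification reproduces the published group totals", {
  published <- readr::read_tsv(
    system.file("extdata", "gene_allele_totals_published.tsv",
                package = "germtriage"),
    show_col_types = FALSE
  )
  g1 <- gene_constraint_summary(
    dplyr::transmute(published, gene = gene, total_alleles = adult_alleles)
  )
  t1 <- constraint_group_totals(g1)
  expect_equal(t1$total_alleles[t1$conservation == "conserved"], 130L)
  expect_equal(t1$total_alleles[t1$conservation == "nonconserved"], 1534L)

  g2 <- gene_constraint_summary(
    dplyr::transmute(published, gene = gene,
                     total_alleles = longevity_alleles)
  )
  t2 <- constraint_group_totals(g2)
  expect_equal(t2$total_alleles[t2$conservation == "conserved"], 6L)
  expect_equal(t2$total_alleles[t2$conservation == "nonconserved"], 48L)

  # conservation split is keyed on LOEUF alone
  expect_equal(g1$conservation[g1$gene == "MSH2"], "conserved")
  expect_equal(g1$conservation[g1$gene == "MAX"], "nonconserved")

  expect_error(
    gene_constraint_summary(tibble::tibble(gene = "ATM",
                                           total_alleles = 1L)),
    "ATM"
  )

  single <- gene_constraint_summary(
    tibble::tibble(gene = "BRCA2", total_alleles = 1L)
  )
  expect_equal(constraint_group_totals(single)$total_alleles, c(0L, 1L))
})

test_that("allele totals are conserved end to end", {
  co <- small_sim(seed = 29)
  decisions <- triage_cohort(apply_filters(co$annotations))
  prev <- prevalence_table(decisions, co$dosage)
  expect_true(all(prev$ac == prev$n_het + 2L * prev$n_hom))
  expect_true(all(prev$carriers == prev$n_het + prev$n_hom))
  expect_true(all(prev$maf >= 0 & prev$maf <= 1))
  totals <- constraint_group_totals(
    gene_constraint_summary(gene_allele_totals(prev))
  )
  expect_equal(sum(totals$total_alleles), sum(prev$ac))
})

test_that("carrier fractions count each sample once", {
  dosage <- matrix(0L, nrow = 100, ncol = 3,
                   dimnames = list(sprintf("S%03d", 1:100),
                                   c("v1", "v2", "v3")))
  dosage["S001", ] <- c(1L, 1L, 1L)   # one sample, three qualifying variants
  dosage["S002", "v2"] <- 2L
  decisions <- tibble::tibble(
    variant_id = c("v1", "v2", "v3"),
    final_tier = c("PV", "LPV", "PV"),
    prevalence_eligible = TRUE
  )
  expect_equal(carrier_fraction(decisions, dosage), 0.02)
})

test_that("carrier-rate estimates recover the planted rate", {
  rate <- 0.02
  m <- 1 - sqrt(1 - rate)     # per-allele frequency giving the target rate
  n <- 2000
  decisions <- tibble::tibble(variant_id = "v", final_tier = "PV",
                              prevalence_eligible = TRUE)
  bound <- 3 * sqrt(rate * (1 - rate) / n) + 1e-12
  inside <- vapply(1:1000, function(r) {
    dos <- simulate_genotypes(c(v = m), n, seed = 50000 + r)
    est <- carrier_fraction(decisions, dos)
    abs(est - rate) <= bound
  }, logical(1))
  expect_gte(mean(inside), 0.99)
})

test_that("cohort comparison intersects by exact key", {
  a <- tibble::tibble(variant_id = c("1:1:A:T", "1:2:A:T"),
                      gene = "BRCA2", final_tier = "PV",
                      ac = c(3L, 1L), maf = c(0.01, 0.003))
  b <- tibble::tibble(variant_id = c("1:3:A:T", "1:4:A:T"),
                      gene = "BRCA2", final_tier = "PV",
                      ac = c(2L, 2L), maf = c(0.02, 0.02))
  expect_equal(nrow(compare_cohorts(a, b)), 0L)

  b$variant_id[1] <- "1:2:A:T"
  shared <- compare_cohorts(a, b)
  expect_equal(nrow(shared), 1L)
  expect_equal(shared$maf_g1, 0.003)
  expect_equal(shared$maf_g2, 0.02)

  co1 <- small_sim(seed = 61, n_variants = 60)
  co2 <- small_sim(seed = 61, n_samples = 90, n_variants = 60)
  p1 <- prevalence_table(triage_cohort(apply_filters(co1$annotations)),
                         co1$dosage)
  p2 <- prevalence_table(triage_cohort(apply_filters(co2$annotations)),
                         co2$dosage)
  shared <- compare_cohorts(p1, p2)
  expect_equal(sort(shared$variant_id),
               sort(intersect(p1$variant_id, p2$variant_id)))
})
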