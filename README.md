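# germtriage

Hybrid triage of rare germline cancer-variant findings in population
cohorts, for researchers running secondary-findings analyses over the 28
cancer genes of the ACMG SF v3.0 reporting list.

Population genome screens surface thousands of rare variants in
well-established cancer genes, far too many for expert review alone.
`germtriage` implements a reproducible hybrid strategy: a filtration
cascade (panel → consequence → gnomAD AF ≤ 5% → ClinVar benign removal),
a deterministic ACMG/AMP 2015 criterion-combination engine, an in-silico
predictor consensus (SIFT < 0.05, PolyPhen2-HDIV ≥ 0.95,
MutationAssessor ≥ 2, M-CAP > 0.025, CADD ≥ 15; conflicts resolved by
REVEL > 0.75 ∧ MetaLR > 0.5), and a ClinVar-review-status-aware decision
tree that auto-reports concordant high-confidence PV/LPV calls, emulates
expert review with deterministic rules over recorded evidence, and labels
computationally supported uncertain variants as **del-VUS** (deleterious
VUS). Variants never submitted to ClinVar can only exit as del-VUS —
novel variants are not promoted without clinical data. RET/MAX
loss-of-function variants are excluded from prevalence statistics
(proto-oncogenes drive cancer through gain of function).

Downstream statistics follow the diploid identities
`ac = n_het + 2·n_hom`, `maf = ac / (2·n_called)`, with per-gene allele
totals stratified by gene constraint (conserved ⇔ LOEUF < 0.35), distinct
per-sample carrier fractions, per-region carrier proportions, and
birth→residence migration matrices. A seeded Hardy–Weinberg
synthetic-cohort generator with planted truth labels makes every stage
testable offline.

## Worked example

```r
library(germtriage)

cohort <- simulate_cohort(sim_config(seed = 1))   # 2,000 samples x 300 variants
paths  <- write_cohort(cohort, "cohort")
run    <- run_pipeline(pipeline_config(paths[["vcf"]],
                                       paths[["annotations"]],
                                       paths[["samples"]]))
run
#> germline triage run
#>   variants in:    300
#>   kept/dropped:   240 / 60
#>   routes:        auto 49, manual 155, discard 36
#>   tiers:          del_VUS=111, excluded=36, LPV=40, PV=53
#>   PV/LPV carrier fraction:  0.156
```

Of 300 annotated variants, 60 decoys fall to the filters; 49 concordant
high-confidence ClinVar×engine calls are reported automatically; 155 go
through the emulated manual review; and the cohort ends with 53 PVs, 40
LPVs and 111 del-VUSs. The most frequent reported variants:

```r
head(run$prevalence[order(-run$prevalence$ac), ], 4)
#>   variant_id         gene  final_tier    ac n_het n_hom     maf
#> 1 13:32495876:C:A    BRCA2 PV            25    23     1 0.00626
#> 2 10:87886617:CTGT:C PTEN  del_VUS       23    21     1 0.00576
#> 3 18:51030255:C:A    SMAD4 del_VUS       22    22     0 0.00551
#> 4 5:113183198:TTG:T  APC   LPV           21    21     0 0.00526
```

Each row carries the allele count, zygosity split and cohort MAF for one
reported variant. `run$group_totals` gives the constraint-stratified
allele totals, `tidy(run)` the full per-variant decision table with its
evidence trail, `glance(run)` a one-row run summary, and `autoplot(run)`
the per-gene tier counts. `write_report_bundle(run, "reports")` writes
all tables plus a JSON manifest. A thin command-line wrapper with
`simulate`, `run` and `classify` subcommands ships in `inst/cli/triage.R`.

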