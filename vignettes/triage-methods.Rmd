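---
title: "Methods: hybrid germline variant triage for population cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid germline variant triage for population cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germtriage)
library(dplyr)
```

## The problem

Population-scale genome sequencing surfaces secondary findings: variants in
well-established cancer-predisposition genes carried by people who were not
sequenced for a cancer indication. The ACMG SF v3.0 reporting list names 28
such genes (BRCA1/2, the mismatch-repair genes, MUTYH, TP53, the SDHx
genes, and others, all autosomal). Interpreting tens of thousands of rare
variants in these genes by hand is impractical and error-prone, so
`germtriage` implements a hybrid strategy: deterministic automation
everywhere the evidence is unambiguous, and a reproducible, rule-encoded
emulation of expert review where it is not.

The pipeline takes three tabular inputs — a multi-sample diploid VCF, a
per-variant annotation table (gene, consequence, gnomAD allele frequency,
ClinVar class and review status, seven in-silico predictor scores, ACMG
criterion flags, optional GoF/LoF labels, and a literature-support flag) —
plus sample metadata, and produces an auditable per-variant decision with
one of four outcomes: pathogenic variant (PV), likely pathogenic variant
(LPV), deleterious VUS (del-VUS: a variant of uncertain significance with
enough computational support to deserve attention), or excluded.

## Pipeline stages

### 1. Filtration cascade

Variants pass four ordered gates; a failing variant records the *first*
failing reason, which makes filter reports additive and auditable:

1. `off_panel` — gene outside the configured panel (default: the 28 genes);
2. `disallowed_class` — consequence outside {nonsynonymous SNV, stop-gain,
   frameshift deletion/insertion, splice site}; synonymous substitutions
   are removed here;
3. `af_above_max` — gnomAD allele frequency strictly above `af_max`
   (default 0.05). The boundary is inclusive-keep: a variant at exactly 5%
   is retained. A variant *absent* from gnomAD is retained — for a
   population screen aimed at rare pathogenic variation, absence from a
   database of ~10^5 genomes is evidence of rarity, not of safety to
   discard;
4. `clinvar_benign` — ClinVar benign or likely benign assertions.

### 2. ACMG/AMP criterion combination

The engine implements the 2015 ACMG/AMP combining rules over the 28
criterion flags (PVS1, PS1–4, PM1–6, PP1–5, BA1, BS1–4, BP1–7). Flags are
inputs: assigning them from raw evidence is the job of upstream annotators,
and which subset an annotator populates varies by tool. Pathogenic requires
PVS1 plus supporting evidence, two strong criteria, or strong+moderate
combinations; likely pathogenic the familiar weaker combinations; BA1 or
two strong benign criteria give benign. When rules fire on both sides the
result is `uncertain` — contradictory evidence is never averaged. The
implementation is verified in the test suite against an independently coded
rule-list oracle on all 2,700 evidence-count combinations.

### 3. In-silico consensus

Five primary predictors vote deleterious at their published thresholds —
SIFT < 0.05, PolyPhen2-HDIV ≥ 0.95, MutationAssessor ≥ 2, M-CAP > 0.025,
CADD ≥ 15 — with the strict/inclusive direction of each inequality
preserved exactly. Three or more votes constitute consensus support; zero
votes (with at least three predictors available) is no support; one or two
votes is a conflict, resolved as supported only when REVEL > 0.75 *and*
MetaLR > 0.5. Two deliberate choices:

* **Missing scores abstain.** A novel variant with sparse annotation is
  not pushed toward benign by absence of data; fewer than three available
  predictors gives `insufficient_data`.
* **A resolved conflict counts as support everywhere.** The REVEL/MetaLR
  step exists precisely to settle conflicted variants, so
  `conflicting_resolved_supported` satisfies every downstream rule that
  asks for in-silico support. Restricting it to a single review rule would
  make the resolution outcome meaningless elsewhere.

### 4. Routing and emulated manual review

Routing crosses the ClinVar class and review status with the engine tier,
in priority order: concordant P/LP calls at expert-panel or
multiple-submitters status are auto-reported; P/LP assertions resting on a
single submitter (or no assertion criteria) always go to manual review;
ClinVar-unsettled variants (VUS, conflicting, not provided, never
submitted) go to manual review only when the engine calls them P/LP; and
expert-panel P/LP variants that the engine under-calls as uncertain are
also manually reviewed rather than silently trusted or discarded.
Everything else is discarded.

Manual review is emulated by deterministic rules over recorded evidence,
so the expert step is reproducible from its inputs:

* novel variants (never submitted to ClinVar) that the engine calls P/LP
  become del-VUS *always* — without clinical case data no novel variant is
  promoted to PV/LPV;
* low-review-status P/LP assertions are confirmed (PV or LPV) only with
  both in-silico support and literature support; with in-silico support
  but no literature they are downgraded to del-VUS;
* ClinVar-uncertain variants with engine support and in-silico support
  become del-VUS;
* everything else is excluded.

The confirmation rule is restricted to single-submitter/no-assertion
status by design: an expert-panel variant arriving at review has, by
construction of the routing, an uncertain engine tier, and we do not
overrule a discordant engine with the same literature flag that tips
weaker assertions. The combined "P/LP" ClinVar class is conservatively
named LPV on confirmation.

### 5. Proto-oncogene exclusion

RET and MAX are the only proto-oncogenes on the panel; their driver
mechanism is gain of function. Variants with proven LoF labels — or
truncating consequences with no label ("potential loss of function") — are
flagged ineligible for prevalence statistics while keeping their triage
tier. GoF-labelled variants stay eligible. The GoF/LoF position summary is
deliberately descriptive (counts, median residue, range, distance from the
protein midpoint); with a handful of variants per label no inferential
statement is defensible.

### 6. Prevalence, constraint, and geography

Allele statistics follow the diploid identities `ac = n_het + 2·n_hom`,
`carriers = n_het + n_hom`, `maf = ac / (2·n_called)`; missing genotypes
leave both numerator and denominator. Reported MAFs are rounded to two
significant figures; full precision is retained internally and in the
companion columns of the report bundle. Gene-level totals are stratified
by constraint: a gene is *conserved* when its LOEUF is below 0.35. The
split is keyed on LOEUF alone — the pLI ranking disagrees near the
boundary (MSH2 at LOEUF 0.334 is conserved despite pLI 0.9; MAX at 0.462
is not despite pLI 0.83) — and the bundled gnomAD v2.1.1-style table can
be replaced by any `gene`/`pli`/`loeuf` TSV. Regional summaries attribute
carriers by residence region (birth region behind a flag) and report
carriers/participants; the migration matrix cross-tabulates birth against
residence, with net flows that sum to zero by construction.

## The synthetic-cohort generator

Real cohorts of this kind are access-controlled, so the generator is a
first-class module: it produces a VCF, annotation table, sample metadata,
and a truth table from one seed, with every variant *planted* into a
triage category whose evidence is constructed to land on a known route and
tier. Genotypes are independent Binomial(2, maf) draws (Hardy–Weinberg,
no relatedness or linkage), with true MAFs log-uniform on [1e-5, 5e-3] —
the rare-variant regime the pipeline targets. Predictor scores are drawn
uniformly within the deleterious or benign side of each published
threshold, hitting the deleterious side independently with probability
`p_hit = 0.9` for deleterious-planted variants; gnomAD AF equals the true
MAF with multiplicative lognormal noise (σ = 0.2) so the frequency filter
is decoupled from the cohort estimate. Decoy variants exercise each
filtration reason. The truth table's expected verdicts are derived by
generator-side bookkeeping from the drawn evidence, independent of the
pipeline's own routing code, so end-to-end recovery is a genuine
two-implementation agreement check.

Defaults are 2,000 samples × 300 variants: large enough that every planted
category and filter reason is populated and allele-statistic identities
are exercised on hundreds of variants, small enough to regenerate freely.
What passing synthetic tests shows is that the *decision logic* is
implemented exactly as specified; it does not show robustness to the
things the generator omits — correlated predictor scores, annotation
version skew between ClinVar and the criterion annotator, population
structure, relatedness, or genotyping error.

## Numerical and representational choices

* **Variant keys** are 1-based VCF-convention `(chrom, pos, ref, alt)`
  tuples, normalized by parsimony trimming: shared trailing bases first,
  then shared leading bases, always keeping one anchor base. Full
  left-alignment across repeat tracts requires flanking reference
  sequence, which an annotation-table pipeline does not carry; trimming
  maps every padded spelling of a fixed event to one canonical key and is
  idempotent. Alleles are capped at 51 characters (50 bp indels plus
  anchor), mirroring small-variant calling limits.
* **Multi-allelic records** decompose into one key per alternate allele;
  per-sample decomposed dosages sum to at most the ploidy.
* **All contigs are treated as diploid autosomes** — every panel gene is
  autosomal, so chrX/Y dosage conventions are out of scope.
* **Estimator-recovery tests** use 3-standard-error bounds with a
  1e-12 guard against ties at the boundary. For the homozygote fraction
  under HWE (p ≈ 1e-4 at the tested maf of 0.01), the bound uses the
  Poisson standard error `sqrt(p/n)`: with such a rare event the exact
  binomial SE's (1−p) factor contracts the bound by just enough to
  exclude an attainable count carrying ~1.5% probability, which would
  make nominal 99% coverage unachievable for reasons of discreteness,
  not correctness.
* **Determinism**: one seed drives generation through separate derived
  streams (sites, genotypes, metadata); identical configurations produce
  byte-identical files, and identical inputs produce identical manifests
  (input MD5 hashes plus per-stage counts).

## Limitations

The manual-review emulation reproduces expert decisions only insofar as
the evidence they used is recorded in the inputs; published review
campaigns report reclassifications (e.g. single-submitter P/LP variants
downgraded to del-VUS) whose per-variant evidence is not public, and those
specific outcomes cannot be reproduced without it. ACMG criterion flags
are consumed, not derived; garbage flags yield garbage tiers. The
constraint stratification inherits whatever constraint release the user
supplies. Cohort MAF is never used for filtering (that is gnomAD's job),
and no statistical comparison between cohorts or regions is performed —
the package reports lists and proportions, matching the descriptive scope
of the underlying study design.
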