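#' Names of the 28 ACMG/AMP evidence criteria
#'
#' The full criterion vocabulary of the 2015 ACMG/AMP framework: PVS1, four
#' strong (PS), six moderate (PM) and five supporting (PP) pathogenic
#' criteria, plus BA1, four strong (BS) and seven supporting (BP) benign
#' criteria. The engine accepts any subset; which criteria an upstream
#' annotator actually populates is the caller's concern.
#'
#' @return Character vector of 28 criterion names.
#' @export
acmg_flag_names <- function() {
  c("PVS1",
    paste0("PS", 1:4),
    paste0("PM", 1:6),
    paste0("PP", 1:5),
    "BA1",
    paste0("BS", 1:4),
    paste0("BP", 1:7))
}

# split semicolon-joined flag strings into per-variant criterion vectors
.parse_flags <- function(flags) {
  flags[is.na(flags)] <- ""
  lapply(strsplit(flags, ";", fixed = TRUE), function(x) x[nzchar(x)])
}

.flag_counts <- function(tokens) {
  bad <- setdiff(tokens, acmg_flag_names())
  if (length(bad) > 0L) {
    stop("unknown ACMG criterion: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tokens <- unique(tokens)
  c(
    pvs = sum(tokens == "PVS1"),
    ps = sum(grepl("^PS", tokens)),
    pm = sum(grepl("^PM", tokens)),
    pp = sum(grepl("^PP", tokens)),
    ba = sum(tokens == "BA1"),
    bs = sum(grepl("^BS", tokens)),
    bp = sum(grepl("^BP", tokens))
  )
}

# ACMG/AMP 2015 combining rules on evidence-strength counts.
# Pathogenic is tested before likely pathogenic; a benign-side and a
# pathogenic-side rule firing together is a contradiction -> uncertain.
.tier_from_counts <- function(pvs, ps, pm, pp, ba, bs, bp) {
  pathogenic <-
    (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm >= 1 && pp >= 1) || pp >= 2)) ||
    ps >= 2 ||
    (ps >= 1 && (pm >= 3 || (pm >= 2 && pp >= 2) || (pm >= 1 && pp >= 4)))
  likely_pathogenic <-
    (pvs >= 1 && pm >= 1) ||
    (ps >= 1 && pm >= 1) ||
    (ps >= 1 && pp >= 2) ||
    pm >= 3 ||
    (pm >= 2 && pp >= 2) ||
    (pm >= 1 && pp >= 4)
  benign <- ba >= 1 || bs >= 2
  likely_benign <- (bs >= 1 && bp >= 1) || bp >= 2
  p_side <- pathogenic || likely_pathogenic
  b_side <- benign || likely_benign
  if (p_side && b_side) return("uncertain")
  if (pathogenic) return("pathogenic")
  if (likely_pathogenic) return("likely_pathogenic")
  if (benign) return("benign")
  if (likely_benign) return("likely_benign")
  "uncertain"
}

#' Combine ACMG/AMP criterion flags into a five-tier classification
#'
#' Deterministic implementation of the 2015 ACMG/AMP combining rules.
#' A variant is pathogenic with PVS1 plus one strong, two moderate, one
#' moderate plus one supporting, or two supporting criteria; with two
#' strong criteria; or with one strong plus three moderate, two moderate
#' and two supporting, or one moderate and four supporting. Likely
#' pathogenic with PVS1 plus one moderate; one strong plus one or two
#' moderate; one strong plus two supporting; three moderate; two moderate
#' plus two supporting; or one moderate plus four supporting. BA1 or two
#' strong benign criteria give benign; one strong benign plus one
#' supporting, or two supporting benign criteria give likely benign.
#' When no rule fires, or rules fire on both sides, the variant is of
#' uncertain significance.
#'
#' @param flags Character vector of semicolon-joined criterion names
#'   (e.g. `"PVS1;PS2"`), or a list of character vectors.
#' @return Character vector with values in `pathogenic`,
#'   `likely_pathogenic`, `uncertain`, `likely_benign`, `benign`.
#' @export
#' @examples
#' combine_acmg(c("PVS1;PS2", "PM2;PP3", "BA1;PVS1;PM2"))
combine_acmg <- function(flags) {
  if (is.character(flags)) flags <- .parse_flags(flags)
  vapply(flags, function(tokens) {
    n <- .flag_counts(tokens)
    .tier_from_counts(n["pvs"], n["ps"], n["pm"], n["pp"],
                      n["ba"], n["bs"], n["bp"])
  }, character(1))
}

#' In-silico predictor consensus
#'
#' Casts one deleterious vote per available primary predictor meeting its
#' published threshold: SIFT < 0.05, PolyPhen2-HDIV >= 0.95,
#' MutationAssessor >= 2, M-CAP > 0.025, CADD >= 15. Three or more votes
#' are consensus support for likely pathogenicity; zero votes with at
#' least three predictors available is no support; one or two votes is a
#' conflict, resolved as supported only when REVEL > 0.75 and
#' MetaLR > 0.5 (a missing resolver resolves against support). Fewer than
#' three available primary predictors yields `insufficient_data`; missing
#' predictors abstain rather than vote benign.
#'
#' @param scores Data frame with numeric columns `sift`, `polyphen2_hdiv`,
#'   `mutation_assessor`, `mcap`, `cadd`, `revel`, `metalr` (NA = missing).
#' @return Tibble with columns `verdict`, `votes_deleterious`,
#'   `votes_available`, one row per input row.
#' @export
#' @examples
#' insilico_consensus(data.frame(
#'   sift = 0.01, polyphen2_hdiv = 0.99, mutation_assessor = NA,
#'   mcap = NA, cadd = 25, revel = NA, metalr = NA
#' ))
insilico_consensus <- function(scores) {
  scores <- tibble::as_tibble(scores)
  need <- c("sift", "polyphen2_hdiv", "mutation_assessor", "mcap", "cadd",
            "revel", "metalr")
  missing_cols <- setdiff(need, names(scores))
  if (length(missing_cols) > 0L) {
    stop("scores lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  votes <- cbind(
    scores$sift < 0.05,
    scores$polyphen2_hdiv >= 0.95,
    scores$mutation_assessor >= 2,
    scores$mcap > 0.025,
    scores$cadd >= 15
  )
  available <- rowSums(!is.na(votes))
  deleterious <- rowSums(votes, na.rm = TRUE)
  resolver <- !is.na(scores$revel) & scores$revel > 0.75 &
    !is.na(scores$metalr) & scores$metalr > 0.5
  verdict <- dplyr::case_when(
    available < 3 ~ "insufficient_data",
    deleterious >= 3 ~ "supported",
    deleterious == 0 ~ "not_supported",
    resolver ~ "conflicting_resolved_supported",
    TRUE ~ "conflicting_resolved_not_supported"
  )
  tibble::tibble(
    verdict = verdict,
    votes_deleterious = as.integer(deleterious),
    votes_available = as.integer(available)
  )
}

# verdicts counted as in-silico support during manual review; the
# REVEL/MetaLR resolution exists to settle conflicted variants, so its
# positive outcome counts as support wherever support is asked for
.supporting_verdicts <- function() {
  c("supported", "conflicting_resolved_supported")
}
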