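#' Per-region carrier proportions
#'
#' Attributes each sample to a region (residence by default, birth behind
#' the flag) and reports per-region participant counts, carrier counts,
#' and the carrier proportion `n_carriers / n_participants`. Samples with
#' a missing region are excluded from the table and counted in the
#' `n_excluded` attribute. Regions with zero participants are omitted.
#'
#' @param samples Sample metadata tibble ([read_sample_metadata()]).
#' @param decisions Triage decision tibble.
#' @param dosage Dosage matrix (rows = samples).
#' @param tiers Qualifying tiers (default `PV`, `LPV`, `del_VUS`).
#' @param region_from Attribute carriers by `"residence"` (default) or
#'   `"birth"` region.
#' @return Tibble with `region`, `n_participants`, `n_carriers`,
#'   `carrier_proportion`; attribute `n_excluded` counts samples with a
#'   missing region.
#' @export
regional_summary <- function(samples, decisions, dosage,
                             tiers = c("PV", "LPV", "del_VUS"),
                             region_from = c("residence", "birth")) {
  region_from <- match.arg(region_from)
  col <- if (region_from == "residence") "residence_region" else
    "birth_region"
  carriers <- .carrier_samples(decisions, dosage, tiers)
  samples$region <- samples[[col]]
  known <- samples[!is.na(samples$region), , drop = FALSE]
  out <- known |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n_participants = dplyr::n(),
      n_carriers = sum(.data$sample_id %in% carriers),
      .groups = "drop"
    ) |>
    dplyr::mutate(carrier_proportion = .data$n_carriers /
                    .data$n_participants)
  attr(out, "n_excluded") <- nrow(samples) - nrow(known)
  out
}

#' Birth-to-residence migration matrix
#'
#' Cross-tabulates participants by birth region (rows) and residence
#' region (columns); the diagonal counts non-migrants. Samples missing
#' either field are excluded and counted. Net flow per region is
#' inflow minus outflow (immigrants minus emigrants) and sums to zero.
#'
#' @param samples Sample metadata tibble.
#' @return Object of class `migration_matrix`: list with `counts` (square
#'   integer matrix over the union of observed regions), `net_flow`
#'   (tibble with `region`, `born`, `residing`, `net`), `n_included`,
#'   `n_excluded`.
#' @export
migration_matrix <- function(samples) {
  ok <- !is.na(samples$birth_region) & !is.na(samples$residence_region)
  inc <- samples[ok, , drop = FALSE]
  regions <- sort(union(inc$birth_region, inc$residence_region))
  counts <- table(
    factor(inc$birth_region, levels = regions),
    factor(inc$residence_region, levels = regions)
  )
  counts <- matrix(as.integer(counts), nrow = length(regions),
                   dimnames = list(birth = regions, residence = regions))
  born <- rowSums(counts)
  residing <- colSums(counts)
  net_flow <- tibble::tibble(
    region = regions,
    born = as.integer(born),
    residing = as.integer(residing),
    net = as.integer(residing - born)
  )
  structure(
    list(counts = counts, net_flow = net_flow,
         n_included = nrow(inc), n_excluded = sum(!ok)),
    class = "migration_matrix"
  )
}

#' @export
print.migration_matrix <- function(x, ...) {
  cat("Birth -> residence migration matrix (", x$n_included,
      " participants, ", x$n_excluded, " excluded for missing region)\n",
      sep = "")
  print(x$counts)
  invisible(x)
}

#' Tidy a migration matrix into long form
#'
#' @param x A `migration_matrix`.
#' @param ... Unused.
#' @return Tibble with `birth_region`, `residence_region`, `n`.
#' @method tidy migration_matrix
#' @export
tidy.migration_matrix <- function(x, ...) {
  long <- as.data.frame(as.table(x$counts), stringsAsFactors = FALSE)
  names(long) <- c("birth_region", "residence_region", "n")
  long$n <- as.integer(long$n)
  tibble::as_tibble(long)
}
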