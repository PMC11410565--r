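#' Bar chart of filtration drop reasons
#'
#' @param filtered Output of [apply_filters()] (or a [filter_report()]
#'   tibble).
#' @return A ggplot object.
#' @export
plot_filter_report <- function(filtered) {
  report <- if (all(c("drop_reason", "n") %in% names(filtered)) &&
                !"kept" %in% names(filtered)) {
    filtered
  } else {
    filter_report(filtered)
  }
  ggplot2::ggplot(report,
                  ggplot2::aes(x = stats::reorder(.data$drop_reason,
                                                  -.data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "drop reason (first failing cascade rule)",
                  y = "variants dropped") +
    ggplot2::theme_minimal()
}

#' Per-gene counts of reported variants by tier
#'
#' @param decisions Triage decision tibble ([triage_cohort()]).
#' @return A ggplot object.
#' @export
plot_gene_tiers <- function(decisions) {
  d <- decisions[decisions$final_tier %in% c("PV", "LPV", "del_VUS"), ,
                 drop = FALSE]
  d$final_tier <- factor(d$final_tier, levels = c("PV", "LPV", "del_VUS"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, fill = .data$final_tier)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(values = c(PV = "#b2182b", LPV = "#ef8a62",
                                          del_VUS = "#67a9cf"),
                               name = "tier") +
    ggplot2::labs(x = NULL, y = "variants") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Regional carrier proportions
#'
#' @param regional Output of [regional_summary()].
#' @return A ggplot object.
#' @export
plot_regional_carriers <- function(regional) {
  ggplot2::ggplot(regional,
                  ggplot2::aes(x = stats::reorder(.data$region,
                                                  -.data$carrier_proportion),
                               y = .data$carrier_proportion)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "carrier proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Heatmap of the birth-to-residence migration matrix
#'
#' @param object A `migration_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot migration_matrix
#' @export
autoplot.migration_matrix <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$residence_region,
                                     y = .data$birth_region,
                                     fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac") +
    ggplot2::labs(x = "residence region", y = "birth region",
                  fill = "participants") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Overview plot of a triage run
#'
#' Per-gene tier counts for the run's reported variants.
#'
#' @param object A `germtriage_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot germtriage_run
#' @export
autoplot.germtriage_run <- function(object, ...) {
  plot_gene_tiers(object$decisions)
}
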