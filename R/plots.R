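#' Plot an ROC curve
#'
#' @param object An `ego_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ego_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("AUC = %.3f%s", object$auc,
                      if (is.null(object$ci)) "" else
                        sprintf("  (%d%% CI %.3f-%.3f)", round(100 * object$level),
                                object$ci[1], object$ci[2]))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of group-level z-scores
#'
#' One panel per node-set pair, bands by metrics, tile colour the bootstrap
#' z-score; cells significant after Bonferroni correction are starred.
#'
#' @param group Output of [group_level_tests()].
#' @return A ggplot.
#' @export
plot_group_heatmap <- function(group) {
  df <- dplyr::mutate(group,
                      pair = paste0(.data$set1, " > ", .data$set2),
                      star = ifelse(.data$significant, "**",
                                    ifelse(!.data$missing & .data$p < 0.05, "*", "")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$band,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$star), size = 3) +
    ggplot2::facet_wrap(~pair) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "metric", y = "band", fill = "z") +
    ggplot2::theme_minimal()
}

#' Plot fractions of significant patients
#'
#' Shows, per band and metric, the fraction of patients whose individual
#' comparison was significant in the hypothesis direction (and against it),
#' one panel per node-set pair.
#'
#' @param summary_tbl Output of [cohort_summary_table()].
#' @return A ggplot.
#' @export
plot_summary_fractions <- function(summary_tbl) {
  df <- summary_tbl |>
    dplyr::mutate(pair = paste0(.data$set1, " > ", .data$set2)) |>
    tidyr::pivot_longer(c("frac_positive", "frac_negative"),
                        names_to = "side", values_to = "fraction") |>
    dplyr::mutate(side = ifelse(.data$side == "frac_positive",
                                "with hypothesis", "against hypothesis"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$band,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(side ~ pair) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "metric", y = "band", fill = "fraction of patients") +
    ggplot2::theme_minimal()
}
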