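# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a reference table
#'
#' Group means with +/- 2 SD whiskers per ratio — the band against which the
#' metacarpal sign is called.
#'
#' @param object A `phalanx_reference`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phalanx_reference <- function(object, ...) {
  g <- object$groups
  ggplot2::ggplot(g, ggplot2::aes(x = .data$age_group, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - 2 * .data$sd,
                                          ymax = .data$mean + 2 * .data$sd)) +
    ggplot2::facet_wrap(~ .data$ratio, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = 1:6) +
    ggplot2::labs(x = "bone-age group", y = "ratio (mean ± 2 SD)",
                  title = "Normative phalangeal ratio reference ranges") +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' Empirical ROC curve (sensitivity against 1 - specificity over all
#' candidate cutoffs) with the chance diagonal; the Youden point is marked
#' when present.
#'
#' @param object A `phalanx_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phalanx_roc <- function(object, ...) {
  curve <- tidy(object)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = 1 - .data$specificity,
                                           y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("AUC %.3f (95%% CI %.3f-%.3f)", object$auc,
                      object$auc_ci_low, object$auc_ci_high)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$youden)) {
    p <- p + ggplot2::annotate(
      "point", x = 1 - object$youden$specificity,
      y = object$youden$sensitivity, colour = "red", size = 2
    )
  }
  p
}

#' Histograms of the three ratios
#'
#' @param ratios Tibble with the three ratio columns; an optional `cohort`
#'   column colours the histograms.
#' @param bins Histogram bin count.
#' @return A ggplot.
#' @export
plot_ratio_distributions <- function(ratios, bins = 60) {
  check_columns(ratios, RATIO_COLS, "ratios table")
  id_cols <- intersect("cohort", names(ratios))
  long <- tidyr::pivot_longer(ratios[c(id_cols, RATIO_COLS)],
                              dplyr::all_of(RATIO_COLS),
                              names_to = "ratio", values_to = "value")
  aes <- if (length(id_cols) > 0) {
    ggplot2::aes(x = .data$value, fill = .data$cohort)
  } else {
    ggplot2::aes(x = .data$value)
  }
  ggplot2::ggplot(long, aes) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.7,
                            position = "identity") +
    ggplot2::facet_wrap(~ .data$ratio, scales = "free") +
    ggplot2::labs(x = "ratio", y = "count") +
    ggplot2::theme_minimal()
}
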