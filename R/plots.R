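# ggplot2 quick-look plots for the main result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Manhattan-style plot of per-site test results
#'
#' Significance of every cytosine along the circular genome, coloured by
#' sequence context, with a dashed line at the selection threshold.
#'
#' @param results Site-result tibble (`position`, `context`, `p_value`).
#' @param alpha Threshold drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, alpha = 0.05) {
  ggplot2::ggplot(
    results[!is.na(results$p_value), ],
    ggplot2::aes(x = .data$position, y = -log10(.data$p_value),
                 colour = .data$context)
  ) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "Position (bp)", y = expression(-log[10](italic(P))),
                  colour = "Context") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.clock_model <- function(object, ...) {
  dat <- object$fit$model
  dat$predicted <- predict(object, dat$score)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$age, y = .data$predicted)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.5) +
    ggplot2::labs(
      x = "Chronological age (years)", y = "Predicted age (years)",
      title = sprintf("Epigenetic clock (R² = %.3f)", object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Box plot of index scores by group and area
#'
#' @param scores Score tibble from [score_samples()] (optionally several
#'   areas bound together).
#' @param groups Character vector aligned with `scores` rows
#'   (`"control"` / `"drug"`).
#' @return A ggplot object.
#' @export
plot_scores <- function(scores, groups) {
  dat <- dplyr::mutate(scores, group = groups)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$area, y = .data$score,
                                    fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = "Index score", fill = NULL) +
    ggplot2::theme_minimal()
}
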