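# Threshold rule and ROC evaluation for the drug-use index classifier.

#' Drug-use index decision threshold
#'
#' `mean(control scores) + 1.96 * SD(control scores)` with the sample SD
#' (n - 1 denominator): the upper bound of the one-sided 97.5% normal
#' range of the control distribution, so the rule's specificity under a
#' Gaussian null is about 0.975.
#'
#' @param control_scores At least two control-group index scores.
#' @return The threshold (a single number).
#' @examples
#' du_threshold(c(8, 10, 12)) # 10 + 1.96 * 2
#' @export
du_threshold <- function(control_scores) {
  if (length(control_scores) < 2L) {
    rlang::abort("Need at least 2 control scores.")
  }
  mean(control_scores) + 1.96 * sd(control_scores)
}

#' Evaluate the threshold classifier
#'
#' A sample is called positive iff its score is **strictly** greater than
#' the threshold. Sensitivity, specificity, PPV and NPV come from the
#' confusion counts; a predictive value whose denominator is zero is
#' returned as `NA` and flagged.
#'
#' @param scores Index scores.
#' @param labels Logical (or 0/1) truth: `TRUE` = drug use.
#' @param threshold Decision cutoff, e.g. from [du_threshold()].
#' @return One-row tibble: confusion counts (`tp`, `fp`, `tn`, `fn`),
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `undefined` (flag).
#' @export
evaluate_classifier <- function(scores, labels, threshold) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    rlang::abort("Both classes must be present.")
  }
  pos <- scores > threshold
  tp <- sum(pos & labels)
  fp <- sum(pos & !labels)
  tn <- sum(!pos & !labels)
  fn <- sum(!pos & labels)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  ppv <- safe_div(tp, tp + fp)
  npv <- safe_div(tn, tn + fn)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = ppv, npv = npv,
    undefined = is.na(ppv) || is.na(npv)
  )
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a threshold and accumulates the ROC by
#' unique score value, so tied scores contribute diagonal segments; the
#' trapezoid area then equals the tie-adjusted Mann-Whitney statistic
#' `U / (n1 * n0)` with ties counted one half.
#'
#' @param scores Index scores.
#' @param labels Logical (or 0/1) truth: `TRUE` = drug use (positive).
#' @return List with `roc_points` (tibble `fpr`, `tpr`, from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    rlang::abort("Both classes must be present.")
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # collapse tied scores into single threshold steps
  last_of_value <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last_of_value]
  fp <- cumsum(!l)[last_of_value]
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(
    roc_points = tibble::tibble(fpr = fpr, tpr = tpr),
    auc = auc
  ), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n",
              nrow(x$roc_points), x$auc))
  invisible(x)
}
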