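# The epigenetic clock: OLS of chronological age on the age-index score,
# and age-acceleration estimation.

#' Fit the epigenetic clock
#'
#' Ordinary least squares of chronological age on the age-index score,
#' trained on the control group. Predicted age is
#' `intercept + coefficient * score`; `r_squared` equals the squared
#' Pearson correlation between age and score.
#'
#' @param ages Chronological ages (years), n >= 8.
#' @param age_index_scores Age-index scores, same order, non-constant.
#' @param sample_ids Optional ids of the training samples (metadata).
#' @return A `clock_model` with `intercept`, `coefficient`, `r_squared`,
#'   `p_value` (slope test), `training_ids`, and the underlying `lm` fit.
#' @export
fit_clock <- function(ages, age_index_scores, sample_ids = NULL) {
  if (length(ages) < 8L) rlang::abort("Need n >= 8 training samples.")
  if (length(ages) != length(age_index_scores)) {
    rlang::abort("`ages` and `age_index_scores` must have equal length.")
  }
  if (length(unique(age_index_scores)) < 2L) {
    rlang::abort("Scores are constant; the clock cannot be fitted.")
  }
  fit <- lm(age ~ score, data = data.frame(age = ages, score = age_index_scores))
  sm <- summary(fit)
  structure(list(
    intercept = unname(coef(fit)[1]),
    coefficient = unname(coef(fit)[2]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients["score", "Pr(>|t|)"],
    training_ids = sample_ids,
    fit = fit
  ), class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf(
    "<clock_model> predicted age = %.3f + %.4f x score (R^2 = %.4f, p = %.3g)\n",
    x$intercept, x$coefficient, x$r_squared, x$p_value
  ))
  invisible(x)
}

#' Predict age from age-index scores
#'
#' @param object A `clock_model`.
#' @param scores Age-index scores.
#' @param ... Unused.
#' @return Predicted ages (years).
#' @export
predict.clock_model <- function(object, scores, ...) {
  object$intercept + object$coefficient * scores
}

#' @export
tidy.clock_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("(Intercept)", "score"),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' @export
glance.clock_model <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    p.value = x$p_value,
    nobs = length(x$fit$residuals)
  )
}

#' Serialise / restore a clock model as JSON
#'
#' Only the linear map and diagnostics are stored, not the `lm` object.
#'
#' @param clock A `clock_model`.
#' @param path File path.
#' @param overwrite Refuse to clobber unless `TRUE`.
#' @return `path` invisibly (write); a reduced `clock_model` (read).
#' @export
write_clock <- function(clock, path, overwrite = FALSE) {
  stopifnot(inherits(clock, "clock_model"))
  check_overwrite(path, overwrite)
  jsonlite::write_json(
    clock[c("intercept", "coefficient", "r_squared", "p_value", "training_ids")],
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_clock
#' @export
read_clock <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(c(raw, list(fit = NULL)), class = "clock_model")
}

#' Age acceleration of each sample under a fitted clock
#'
#' `acceleration = predicted age - chronological age`. Heroin-positive
#' individuals are retained in the table but marked `excluded`, because
#' heroin has a reported rejuvenating rather than accelerating effect and
#' is left out of group contrasts.
#'
#' @param clock A `clock_model`.
#' @param scores Age-index scores.
#' @param ages Chronological ages, same order.
#' @param heroin Logical flags marking heroin-positive individuals
#'   (default none).
#' @param ids Optional sample ids.
#' @return Tibble: `id`, `score`, `age`, `predicted_age`, `acceleration`,
#'   `excluded`.
#' @export
age_acceleration <- function(clock, scores, ages, heroin = FALSE, ids = NULL) {
  stopifnot(inherits(clock, "clock_model"))
  heroin <- rep_len(as.logical(heroin), length(scores))
  pred <- predict(clock, scores)
  tibble::tibble(
    id = ids %||% as.character(seq_along(scores)),
    score = scores, age = ages,
    predicted_age = pred,
    acceleration = pred - ages,
    excluded = heroin
  )
}

#' Group contrast of age acceleration
#'
#' Compares acceleration in a (sub)group of drug-use individuals against
#' controls with the Mann-Whitney U test, after dropping excluded
#' (heroin-positive) individuals.
#'
#' @param accel Tibble from [age_acceleration()].
#' @param groups Character vector aligned with `accel` rows: `"control"`
#'   or `"drug"`.
#' @param subset_mask Optional logical mask restricting the drug side
#'   (e.g. ketamine-positive only).
#' @return One-row tibble: `n_drug`, `n_control`, `median_shift`
#'   (difference in median acceleration, drug minus control), `p_value`.
#' @export
acceleration_contrast <- function(accel, groups, subset_mask = NULL) {
  keep <- !accel$excluded
  drug_side <- keep & groups == "drug"
  if (!is.null(subset_mask)) drug_side <- drug_side & subset_mask
  ctrl_side <- keep & groups == "control"
  if (!any(drug_side) || !any(ctrl_side)) {
    rlang::abort("Both contrast groups must be non-empty.")
  }
  a_drug <- accel$acceleration[drug_side]
  a_ctrl <- accel$acceleration[ctrl_side]
  mw <- mann_whitney(a_drug, a_ctrl)
  tibble::tibble(
    n_drug = length(a_drug), n_control = length(a_ctrl),
    median_shift = median(a_drug) - median(a_ctrl),
    p_value = mw$p_value
  )
}
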