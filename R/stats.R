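# Per-site and cohort-level statistical tests.

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on within-individual differences. Zero
#' differences are dropped (Wilcoxon's rule) and ties among the absolute
#' differences are mid-ranked. The null distribution is computed exactly —
#' by a generating-function convolution over the (possibly tied) ranks —
#' whenever at most 25 non-zero differences remain; beyond that a
#' tie-corrected normal approximation is used. When every difference is
#' zero the test is degenerate and p = 1 is returned with a flag.
#'
#' @param levels_a,levels_b Paired numeric vectors (same individuals, same
#'   order), length >= 5.
#' @return One-row tibble: `statistic` (rank sum of positive differences),
#'   `p_value`, `n_nonzero`, `method` (`"exact"` or `"normal"`),
#'   `degenerate`.
#' @export
paired_wilcoxon <- function(levels_a, levels_b) {
  if (length(levels_a) != length(levels_b)) {
    rlang::abort("Paired vectors must have equal length.")
  }
  if (length(levels_a) < 5L) rlang::abort("Need at least 5 pairs.")
  d <- levels_a - levels_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(tibble::tibble(statistic = NA_real_, p_value = 1, n_nonzero = 0L,
                          method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25L) {
    # Exact null over mid-ranks: double the ranks so tied mid-ranks become
    # integers, then convolve (1 + x^(2 r_i)) / 2 over sites.
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- c(1, rep(0, total))
    for (ri in r2) {
      g <- f / 2
      g[(ri + 1):(total + 1)] <- g[(ri + 1):(total + 1)] + f[1:(total + 1 - ri)] / 2
      f <- g
    }
    w2 <- round(2 * w)
    mu2 <- total / 2
    support <- 0:total
    p <- sum(f[abs(support - mu2) >= abs(w2 - mu2) - 1e-9])
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)  # tie correction via mid-rank squares
    p <- 2 * pnorm(-abs(w - mu) / sigma)
    method <- "normal"
  }
  tibble::tibble(statistic = w, p_value = min(p, 1), n_nonzero = n,
                 method = method, degenerate = FALSE)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The exact null distribution (via the standard
#' rank-sum distribution) is used when `m + n <= 20` and there are no ties;
#' otherwise a tie-corrected normal approximation. No continuity
#' correction is applied, which keeps the U statistic exactly consistent
#' with the ROC area identity `AUC = U / (m n)`.
#'
#' @param x,y Numeric samples (both non-empty).
#' @return One-row tibble: `statistic` (U for `x`), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y) {
  m <- length(x)
  n <- length(y)
  if (m == 0L || n == 0L) rlang::abort("Both samples must be non-empty.")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (m + n <= 20L && !ties) {
    lower <- pwilcox(u, m, n)
    upper <- 1 - pwilcox(u - 1, m, n)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    nn <- m + n
    tie_tab <- table(c(x, y))
    sigma2 <- m * n / 12 * ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      p <- 2 * pnorm(-abs(u - m * n / 2) / sqrt(sigma2))
    }
    method <- "normal"
  }
  tibble::tibble(statistic = u, p_value = p, method = method)
}

#' Log fold change between two group means
#'
#' Natural log of the ratio of per-site mean methylation levels
#' (percent), with a pseudocount guarding against zero means at the low
#' methylation levels typical of mitochondrial DNA.
#'
#' @param mean_a,mean_b Nonnegative group means (percent). Vectorised.
#' @param pseudocount Added to both means; default 0.01 percent.
#' @return `log((mean_a + pseudocount) / (mean_b + pseudocount))`.
#' @export
log_fold_change <- function(mean_a, mean_b, pseudocount = 0.01) {
  if (any(mean_a < 0) || any(mean_b < 0)) {
    rlang::abort("Means must be nonnegative.")
  }
  if (pseudocount == 0 && any(mean_a == 0 & mean_b == 0)) {
    rlang::abort("Both means zero with zero pseudocount: fold change undefined.")
  }
  log((mean_a + pseudocount) / (mean_b + pseudocount))
}

# Build a model frame from a covariate tibble (age, batch, collector,
# alcohol, pmi_class), tolerating a NULL covariate set.
covariate_frame <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  cov <- as.data.frame(covariates)
  stopifnot(nrow(cov) == n)
  for (col in c("batch", "collector", "pmi_class")) {
    if (col %in% names(cov)) cov[[col]] <- factor(cov[[col]])
  }
  cov[, intersect(c("age", "batch", "collector", "alcohol", "pmi_class"),
                  names(cov)), drop = FALSE]
}

# Drop factor covariates with a single observed level (rank-deficiency guard).
drop_constant_terms <- function(cov) {
  if (is.null(cov)) return(NULL)
  keep <- vapply(cov, function(v) length(unique(v)) > 1L, logical(1))
  cov <- cov[, keep, drop = FALSE]
  if (ncol(cov) == 0L) NULL else cov
}

#' Per-site logistic regression of group on methylation level
#'
#' Fits `group ~ level + age + batch + collector + alcohol + pmi_class`
#' by maximum-likelihood logistic regression and returns the methylation
#' coefficient — the log odds ratio of drug-group membership per percentage
#' point of methylation — with its Wald two-sided p-value. Degenerate fits
#' (constant predictor, non-convergence, quasi-separation) are flagged
#' rather than reported as infinite effects.
#'
#' @param group_labels Binary labels: `TRUE`/1 for the drug group.
#' @param site_levels Methylation levels in percent, one per sample.
#' @param covariates Optional tibble of per-sample covariates (`age`,
#'   `batch`, `collector`, `alcohol`, `pmi_class`).
#' @return One-row tibble: `effect` (log OR), `p_value`, `flagged`.
#' @export
site_logistic <- function(group_labels, site_levels, covariates = NULL) {
  y <- as.integer(as.logical(group_labels))
  if (length(unique(y)) < 2L) rlang::abort("Both groups must be represented.")
  if (length(unique(site_levels)) < 2L) {
    return(tibble::tibble(effect = NA_real_, p_value = NA_real_, flagged = TRUE))
  }
  cov <- drop_constant_terms(covariate_frame(covariates, length(y)))
  dat <- data.frame(.y = y, level = site_levels)
  if (!is.null(cov)) dat <- cbind(dat, cov)
  fit <- suppressWarnings(
    glm(.y ~ ., data = dat, family = binomial())
  )
  sm <- suppressWarnings(summary(fit)$coefficients)
  # flag on the methylation coefficient only: quasi-separation on a sparse
  # nuisance covariate (e.g. an empty batch cell) inflates that covariate's
  # SE without invalidating the level coefficient's Wald test
  if (!"level" %in% rownames(sm) ||
      !is.finite(sm["level", "Std. Error"]) || sm["level", "Std. Error"] > 50) {
    return(tibble::tibble(effect = NA_real_, p_value = NA_real_, flagged = TRUE))
  }
  tibble::tibble(effect = sm["level", "Estimate"],
                 p_value = sm["level", "Pr(>|z|)"], flagged = FALSE)
}

#' Per-site association between methylation and age
#'
#' Fits `level ~ age + batch + collector + alcohol + pmi_class` by least
#' squares and returns the age coefficient (percent methylation per year)
#' with its two-sided p-value. With no covariates the coefficient equals
#' the Pearson-correlation slope `r * s_level / s_age`.
#'
#' @param site_levels Methylation levels in percent.
#' @param ages Chronological ages in years (non-constant).
#' @param covariates Optional per-sample covariate tibble (without `age`).
#' @return One-row tibble: `effect` (slope, %/year), `p_value`, `flagged`.
#' @export
site_age_association <- function(site_levels, ages, covariates = NULL) {
  if (length(site_levels) < 8L) rlang::abort("Need n >= 8 samples.")
  if (length(unique(ages)) < 2L) rlang::abort("Ages must be non-constant.")
  cov <- covariate_frame(covariates, length(ages))
  if (!is.null(cov)) cov$age <- NULL
  cov <- drop_constant_terms(cov)
  dat <- data.frame(level = site_levels, age = ages)
  if (!is.null(cov)) dat <- cbind(dat, cov)
  fit <- lm(level ~ ., data = dat)
  sm <- summary(fit)$coefficients
  if (!"age" %in% rownames(sm) || !is.finite(sm["age", "Std. Error"])) {
    return(tibble::tibble(effect = NA_real_, p_value = NA_real_, flagged = TRUE))
  }
  tibble::tibble(effect = sm["age", "Estimate"],
                 p_value = sm["age", "Pr(>|t|)"], flagged = FALSE)
}

#' Select sites below a p-value threshold
#'
#' Retains results with `p_value < alpha`. Deliberately applies no
#' multiple-testing adjustment: site selection for the weighted indices is
#' threshold-based, with the threshold itself varied in the sensitivity
#' analyses (0.05, 0.02, 0.005).
#'
#' @param results Site-result tibble with a `p_value` column (and
#'   optionally a `flagged` column; flagged rows are never selected).
#' @param alpha Threshold in (0, 1).
#' @return The selected rows.
#' @export
select_sites <- function(results, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) rlang::abort("`alpha` must be in (0, 1).")
  ok <- !is.na(results$p_value) & results$p_value < alpha
  if ("flagged" %in% names(results)) ok <- ok & !results$flagged
  results[ok, , drop = FALSE]
}

#' Pearson chi-square test of independence
#'
#' Pearson chi-square on an r x c contingency table, without continuity
#' correction, with `df = (r - 1)(c - 1)` and an upper-tail p-value.
#'
#' @param table Matrix of nonnegative counts with positive row and column
#'   sums.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) rlang::abort("Counts must be nonnegative.")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    rlang::abort("Zero marginal row/column.")
  }
  res <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value))
}

#' Power of the two-sided test of zero Pearson correlation
#'
#' Closed form via the Fisher z transform:
#' `power = Phi(sqrt(n - 3) * atanh(r) - z_{1 - alpha/2})`.
#'
#' @param r True correlation, in (0, 1).
#' @param n Sample size (> 3).
#' @param alpha Two-sided significance level.
#' @return Power as a number in (0, 1).
#' @examples
#' pearson_power(0.5, 39) # > 0.9
#' @export
pearson_power <- function(r, n, alpha = 0.05) {
  if (r <= 0 || r >= 1) rlang::abort("`r` must be in (0, 1).")
  if (n <= 3) rlang::abort("`n` must exceed 3.")
  pnorm(sqrt(n - 3) * atanh(r) - qnorm(1 - alpha / 2))
}
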