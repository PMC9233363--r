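# Drivers applying the per-site tests across a methylation matrix.

# Align matrix columns to a cohort table; returns cohort rows in
# matrix-sample order.
cohort_for_matrix <- function(mat, cohort) {
  idx <- match(mat$samples$individual_id, cohort$individual_id)
  if (anyNA(idx)) rlang::abort("Matrix samples missing from the cohort table.")
  cohort[idx, ]
}

#' Per-site brain-area contrast between paired matrices
#'
#' For every site shared between the two areas, runs the paired Wilcoxon
#' signed-rank test across individuals present in both matrices and
#' attaches the log fold change of area-A over area-B mean methylation as
#' the effect (the future index weight).
#'
#' @param mat_a,mat_b `methylation_matrix` objects for the two areas
#'   (conventionally NAcc and PFC), sharing individuals.
#' @param pseudocount Passed to [log_fold_change()].
#' @return Site-result tibble: `position`, `strand`, `context`, `effect`,
#'   `p_value`, `test_kind = "paired_wilcoxon_lfc"`, `flagged`.
#' @export
ba_site_tests <- function(mat_a, mat_b, pseudocount = 0.01) {
  paired_ids <- intersect(mat_a$samples$individual_id,
                          mat_b$samples$individual_id)
  if (length(paired_ids) < 5L) rlang::abort("Need >= 5 paired individuals.")
  shared <- overlap_sites(mat_a, mat_b)
  if (nrow(shared) == 0L) {
    rlang::abort("No sites shared between the two matrices.")
  }
  col_a <- match(paired_ids, mat_a$samples$individual_id)
  col_b <- match(paired_ids, mat_b$samples$individual_id)
  row_a <- match(paste(shared$position, shared$strand),
                 paste(mat_a$sites$position, mat_a$sites$strand))
  row_b <- match(paste(shared$position, shared$strand),
                 paste(mat_b$sites$position, mat_b$sites$strand))
  res <- purrr::map_dfr(seq_len(nrow(shared)), function(i) {
    la <- mat_a$levels[row_a[i], col_a]
    lb <- mat_b$levels[row_b[i], col_b]
    wt <- paired_wilcoxon(la, lb)
    tibble::tibble(
      effect = log_fold_change(mean(la), mean(lb), pseudocount),
      p_value = wt$p_value,
      flagged = wt$degenerate
    )
  })
  dplyr::bind_cols(shared, res,
                   tibble::tibble(test_kind = rep("paired_wilcoxon_lfc",
                                                  nrow(shared))))
}

#' Per-site drug-use logistic regressions across a matrix
#'
#' Runs [site_logistic()] at every site of a matrix, taking group labels
#' and covariates (age, batch, collector, alcohol, postmortem-interval
#' class) from the cohort table.
#'
#' @param mat A `methylation_matrix` containing both groups.
#' @param cohort Cohort tibble.
#' @return Site-result tibble with `effect` (log OR), `p_value`,
#'   `test_kind = "logistic_log_or"`, `flagged`.
#' @export
du_site_tests <- function(mat, cohort) {
  info <- cohort_for_matrix(mat, cohort)
  labels <- info$group == "drug"
  covs <- info[, c("age", "batch", "collector", "alcohol", "pmi_class")]
  res <- purrr::map_dfr(seq_len(nrow(mat$sites)), function(i) {
    site_logistic(labels, mat$levels[i, ], covs)
  })
  dplyr::bind_cols(mat$sites, res,
                   tibble::tibble(test_kind = rep("logistic_log_or",
                                                  nrow(mat$sites))))
}

#' Per-site age associations across a matrix
#'
#' Runs [site_age_association()] at every site, with batch, collector,
#' alcohol, and postmortem-interval class as control variables.
#'
#' @param mat A `methylation_matrix` (conventionally controls only).
#' @param cohort Cohort tibble.
#' @return Site-result tibble with `effect` (slope, percent/year),
#'   `p_value`, `test_kind = "age_slope"`, `flagged`.
#' @export
age_site_tests <- function(mat, cohort) {
  info <- cohort_for_matrix(mat, cohort)
  covs <- info[, c("batch", "collector", "alcohol", "pmi_class")]
  res <- purrr::map_dfr(seq_len(nrow(mat$sites)), function(i) {
    site_age_association(mat$levels[i, ], info$age, covs)
  })
  dplyr::bind_cols(mat$sites, res,
                   tibble::tibble(test_kind = rep("age_slope",
                                                  nrow(mat$sites))))
}
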