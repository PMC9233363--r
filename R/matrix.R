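#' Methylation level in percent
#'
#' `100 * num_c / (num_c + num_t)`: the percentage of reads supporting
#' methylation at a cytosine. Zero-coverage input is an error — callers are
#' expected to have applied the coverage filter first.
#'
#' @param num_c Methylated read count(s).
#' @param num_t Unmethylated read count(s).
#' @return Numeric vector of percentages in `[0, 100]`.
#' @examples
#' methylation_level(30, 70) # 30
#' @export
methylation_level <- function(num_c, num_t) {
  if (any(num_c < 0) || any(num_t < 0)) {
    rlang::abort("Counts must be nonnegative.")
  }
  cov <- num_c + num_t
  if (any(cov == 0)) {
    rlang::abort("Zero coverage: filter calls by coverage before computing levels.")
  }
  100 * num_c / cov
}

#' Filter calls by minimum coverage
#'
#' Retains exactly the calls whose total read depth
#' (methylated + unmethylated) is at least `min_coverage`. The default of 30
#' is the stringent depth cut-off applied throughout the analysis.
#'
#' @param calls Call tibble with `count_methylated` and `count_unmethylated`.
#' @param min_coverage Minimum depth (>= 1).
#' @return The retained rows of `calls`.
#' @export
filter_by_coverage <- function(calls, min_coverage = 30) {
  if (min_coverage < 1) rlang::abort("`min_coverage` must be >= 1.")
  dplyr::filter(
    calls, .data$count_methylated + .data$count_unmethylated >= min_coverage
  )
}

#' Assemble an analysis-ready methylation matrix for one brain area
#'
#' A site enters the matrix only if it reaches `min_coverage` in **every**
#' sample of the area ("detectable in all samples"), so the level grid is
#' fully populated by construction. Sites are sorted by position then
#' strand.
#'
#' @param calls Long call tibble (as from [simulate_methylation()] or
#'   [read_report_set()]), with `individual_id`, `area`, `position`,
#'   `strand`, `context`, counts.
#' @param min_coverage Per-cell minimum depth.
#' @param area Optional area to subset to; required when `calls` spans
#'   several areas.
#' @return A `methylation_matrix`: list with `sites` (tibble), `samples`
#'   (tibble), `levels` and `coverage` (numeric matrices, sites x samples).
#' @export
build_matrix <- function(calls, min_coverage = 30, area = NULL) {
  if (!is.null(area)) calls <- calls[calls$area == area, ]
  areas <- unique(calls$area)
  if (length(areas) != 1L) {
    rlang::abort("`calls` must cover exactly one area; pass `area =` to subset.")
  }
  samples <- dplyr::distinct(calls, .data$individual_id, .data$area)
  if (nrow(samples) < 2L) rlang::abort("Need at least 2 samples.")
  samples$sample_id <- paste(samples$individual_id, samples$area, sep = "_")

  dup <- dplyr::count(calls, .data$individual_id, .data$position, .data$strand)
  if (any(dup$n > 1L)) {
    rlang::abort("Duplicate (position, strand) within one sample.")
  }

  kept <- filter_by_coverage(calls, min_coverage)
  # presence rule: site must survive the coverage filter in every sample
  site_counts <- dplyr::count(kept, .data$position, .data$strand)
  full <- site_counts[site_counts$n == nrow(samples), c("position", "strand")]
  kept <- dplyr::inner_join(kept, full, by = c("position", "strand"))
  if (nrow(full) == 0L) {
    sites <- tibble::tibble(position = integer(0), strand = character(0),
                            context = character(0))
    return(structure(list(
      sites = sites, samples = samples,
      levels = matrix(numeric(0), 0, nrow(samples),
                      dimnames = list(NULL, samples$sample_id)),
      coverage = matrix(numeric(0), 0, nrow(samples),
                        dimnames = list(NULL, samples$sample_id))
    ), class = "methylation_matrix"))
  }

  sites <- dplyr::arrange(
    dplyr::distinct(kept, .data$position, .data$strand, .data$context),
    .data$position, .data$strand
  )
  site_key <- paste(sites$position, sites$strand)
  row_idx <- match(paste(kept$position, kept$strand), site_key)
  col_idx <- match(kept$individual_id, samples$individual_id)
  cov <- kept$count_methylated + kept$count_unmethylated
  lv <- matrix(NA_real_, nrow(sites), nrow(samples),
               dimnames = list(NULL, samples$sample_id))
  cv <- lv
  lv[cbind(row_idx, col_idx)] <- methylation_level(kept$count_methylated,
                                                   kept$count_unmethylated)
  cv[cbind(row_idx, col_idx)] <- cov
  stopifnot(!anyNA(lv))
  structure(list(sites = sites, samples = samples, levels = lv, coverage = cv),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf(
    "<methylation_matrix> %d sites x %d samples (area %s)\n",
    nrow(x$sites), nrow(x$samples), unique(x$samples$area)
  ))
  invisible(x)
}

#' Tidy a methylation matrix into a long tibble
#'
#' @param x A `methylation_matrix`.
#' @param ... Unused.
#' @return Long tibble: one row per site x sample with `level` (percent)
#'   and `coverage`.
#' @export
tidy.methylation_matrix <- function(x, ...) {
  if (nrow(x$sites) == 0L) {
    return(tibble::tibble(position = integer(0), strand = character(0),
                          context = character(0), sample_id = character(0),
                          individual_id = character(0), area = character(0),
                          level = numeric(0), coverage = numeric(0)))
  }
  grid <- tidyr::expand_grid(
    site = seq_len(nrow(x$sites)), samp = seq_len(nrow(x$samples))
  )
  tibble::tibble(
    position = x$sites$position[grid$site],
    strand = x$sites$strand[grid$site],
    context = x$sites$context[grid$site],
    sample_id = x$samples$sample_id[grid$samp],
    individual_id = x$samples$individual_id[grid$samp],
    area = x$samples$area[grid$samp],
    level = x$levels[cbind(grid$site, grid$samp)],
    coverage = x$coverage[cbind(grid$site, grid$samp)]
  )
}

#' Subset a methylation matrix by sample or by sequence context
#'
#' @param x A `methylation_matrix`.
#' @param individual_ids Keep only these individuals (default all).
#' @param context_subset `"all"`, `"CpG_only"`, or `"nonCpG_only"`.
#' @return A `methylation_matrix`.
#' @export
subset_matrix <- function(x, individual_ids = NULL, context_subset = "all") {
  stopifnot(inherits(x, "methylation_matrix"))
  keep_s <- rep(TRUE, nrow(x$samples))
  if (!is.null(individual_ids)) {
    keep_s <- x$samples$individual_id %in% individual_ids
  }
  keep_r <- switch(context_subset,
    all = rep(TRUE, nrow(x$sites)),
    CpG_only = x$sites$context == "CpG",
    nonCpG_only = x$sites$context != "CpG",
    rlang::abort('`context_subset` must be "all", "CpG_only" or "nonCpG_only".')
  )
  structure(list(
    sites = x$sites[keep_r, , drop = FALSE],
    samples = x$samples[keep_s, , drop = FALSE],
    levels = x$levels[keep_r, keep_s, drop = FALSE],
    coverage = x$coverage[keep_r, keep_s, drop = FALSE]
  ), class = "methylation_matrix")
}

#' Sites shared between two methylation matrices
#'
#' Intersection keyed by (position, strand); the result is sorted by
#' position then strand so it is stable under input order.
#'
#' @param matrix_a,matrix_b `methylation_matrix` objects over the same
#'   reference.
#' @return Tibble of shared `position`, `strand`, `context`.
#' @export
overlap_sites <- function(matrix_a, matrix_b) {
  shared <- dplyr::inner_join(
    matrix_a$sites, matrix_b$sites[, c("position", "strand")],
    by = c("position", "strand")
  )
  dplyr::arrange(shared, .data$position, .data$strand)
}
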