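# Weighted methylation indices: BA_index, Age_index, DU_index.

INDEX_PROVENANCE <- c(BA = "paired_wilcoxon_lfc",
                      Age = "age_slope",
                      DU = "logistic_log_or")

#' Build a weighted methylation index from selected site results
#'
#' An index is a weighted sum `sum(beta_i * M_i)` over selected cytosines,
#' where `M_i` is the methylation level in percent and `beta_i` the
#' site's effect from the matching per-site test: log fold change for the
#' brain-area index, age slope for the age index, log odds ratio for the
#' drug-use index. Weights are copied verbatim from the results.
#'
#' @param selected_results Non-empty site-result tibble (already
#'   thresholded with [select_sites()]); all rows must carry the test kind
#'   matching `kind`.
#' @param kind `"BA"`, `"Age"`, or `"DU"`.
#' @param alpha The selection threshold that produced the rows (metadata).
#' @param area Area label (`"NAcc"`, `"PFC"`, or `"paired"`).
#' @return An `index_model`.
#' @export
build_index <- function(selected_results, kind = c("BA", "Age", "DU"),
                        alpha = 0.05, area = "paired") {
  kind <- match.arg(kind)
  if (is.null(selected_results) || nrow(selected_results) == 0L) {
    rlang::abort(sprintf(
      "Empty selection for the %s index: no site passed the threshold; try a looser alpha.",
      kind
    ))
  }
  expected <- INDEX_PROVENANCE[[kind]]
  if (!all(selected_results$test_kind == expected)) {
    rlang::abort(sprintf(
      "Mixed or mismatched test kinds: %s index requires '%s' results.",
      kind, expected
    ))
  }
  if (any(!is.finite(selected_results$effect)) ||
      any(selected_results$effect == 0)) {
    rlang::abort("Index weights must be finite and nonzero.")
  }
  entries <- selected_results[, c("position", "strand", "context", "effect")]
  names(entries)[names(entries) == "effect"] <- "weight"
  if (anyDuplicated(paste(entries$position, entries$strand))) {
    rlang::abort("Duplicate sites in index selection.")
  }
  structure(list(kind = kind, entries = entries, selection_alpha = alpha,
                 area = area, provenance = expected),
            class = "index_model")
}

#' @export
print.index_model <- function(x, ...) {
  cat(sprintf("<index_model> %s_index: %d sites (alpha = %g, area = %s)\n",
              x$kind, nrow(x$entries), x$selection_alpha, x$area))
  invisible(x)
}

#' Score samples with a weighted methylation index
#'
#' `score = sum(weight_i * level_i)` with levels in percent. Every index
#' site must be present in the matrix.
#'
#' @param index An `index_model`.
#' @param matrix A `methylation_matrix`.
#' @return Tibble: `sample_id`, `individual_id`, `area`, `score`.
#' @export
score_samples <- function(index, matrix) {
  stopifnot(inherits(index, "index_model"),
            inherits(matrix, "methylation_matrix"))
  key_m <- paste(matrix$sites$position, matrix$sites$strand)
  key_i <- paste(index$entries$position, index$entries$strand)
  idx <- match(key_i, key_m)
  if (anyNA(idx)) {
    rlang::abort(sprintf(
      "Index sites missing from matrix: %s",
      paste(key_i[is.na(idx)], collapse = ", ")
    ))
  }
  scores <- as.numeric(index$entries$weight %*%
                         matrix$levels[idx, , drop = FALSE])
  tibble::tibble(
    sample_id = matrix$samples$sample_id,
    individual_id = matrix$samples$individual_id,
    area = matrix$samples$area,
    score = scores
  )
}

#' Serialise / restore an index model as JSON
#'
#' @param index An `index_model`.
#' @param path File path.
#' @param overwrite Refuse to clobber unless `TRUE`.
#' @return `path` invisibly (write); an `index_model` (read).
#' @export
write_index <- function(index, path, overwrite = FALSE) {
  stopifnot(inherits(index, "index_model"))
  check_overwrite(path, overwrite)
  jsonlite::write_json(unclass(index), path, digits = NA,
                       dataframe = "columns", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(kind = raw$kind,
                 entries = tibble::as_tibble(raw$entries),
                 selection_alpha = raw$selection_alpha,
                 area = raw$area, provenance = raw$provenance),
            class = "index_model")
}

#' Overlap of sites between indices (Venn counts)
#'
#' Counts the sites, keyed by (position, strand), falling in every
#' exclusive intersection cell of the given index models, plus the number
#' shared by at least two models.
#'
#' @param ... Two or more `index_model` objects, or a single named list of
#'   them.
#' @return List with `cells` (tibble: membership pattern, `n`, per-model
#'   logical columns) and `n_shared_by_two_or_more`.
#' @export
venn_overlap <- function(...) {
  models <- list(...)
  if (length(models) == 1L && !inherits(models[[1]], "index_model")) {
    models <- models[[1]]
  }
  if (length(models) < 2L) rlang::abort("Need at least 2 index models.")
  if (is.null(names(models)) || any(names(models) == "")) {
    names(models) <- paste0(
      vapply(models, function(m) m$kind, character(1)), "_",
      vapply(models, function(m) m$area, character(1))
    )
  }
  keys <- lapply(models, function(m) paste(m$entries$position, m$entries$strand))
  universe <- unique(unlist(keys))
  member <- vapply(keys, function(k) universe %in% k,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(NULL, names(models)))
  pattern <- apply(member, 1L, function(row) {
    paste(names(models)[row], collapse = "&")
  })
  cells <- dplyr::count(tibble::tibble(cell = pattern), .data$cell, name = "n")
  list(
    cells = dplyr::arrange(cells, dplyr::desc(.data$n)),
    n_shared_by_two_or_more = sum(rowSums(member) >= 2)
  )
}
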