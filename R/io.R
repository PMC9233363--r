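# Readers and writers for the on-disk artifact formats. All tables are
# plain tab-delimited text so datasets round-trip exactly.

REPORT_COLS <- c("position", "strand", "count_methylated",
                 "count_unmethylated", "context", "trinucleotide")

check_overwrite <- function(path, overwrite) {
  if (file.exists(path) && !overwrite) {
    rlang::abort(sprintf("`%s` exists; pass overwrite = TRUE to replace it.", path))
  }
}

#' Write a per-sample cytosine report
#'
#' Emits the tab-delimited cytosine-report dialect used throughout the
#' package (Bismark-style column order): position (1-based on the circular
#' reference), strand (`+` = H-chain, `-` = L-chain), methylated count,
#' unmethylated count, context, trinucleotide.
#'
#' @param calls Tibble of calls for one sample, with the `REPORT` columns.
#' @param path Output file path.
#' @param overwrite Refuse to clobber an existing file unless `TRUE`.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(calls, path, overwrite = FALSE) {
  if (is.null(calls) || nrow(calls) == 0L) {
    rlang::abort("Refusing to write an empty cytosine report.")
  }
  missing_cols <- setdiff(REPORT_COLS, names(calls))
  if (length(missing_cols) > 0) {
    rlang::abort(paste("Missing columns:", paste(missing_cols, collapse = ", ")))
  }
  check_overwrite(path, overwrite)
  readr::write_tsv(calls[, REPORT_COLS], path, col_names = TRUE)
  invisible(path)
}

#' Read a cytosine report
#'
#' Parses one sample's tab-delimited cytosine report, validates every row,
#' and attaches the methylation level in percent. Malformed rows are
#' reported with their line numbers.
#'
#' @param path Path to a file written by [write_cytosine_report()].
#' @param genome_length Optional reference length for position range checks.
#' @return A tibble of calls with a `level` column (percent; `NA` where
#'   coverage is zero).
#' @export
read_cytosine_report <- function(path, genome_length = NULL) {
  if (!file.exists(path)) rlang::abort(sprintf("No such file: %s", path))
  calls <- readr::read_tsv(
    path,
    col_types = readr::cols(
      position = readr::col_integer(),
      strand = readr::col_character(),
      count_methylated = readr::col_integer(),
      count_unmethylated = readr::col_integer(),
      context = readr::col_character(),
      trinucleotide = readr::col_character()
    )
  )
  missing_cols <- setdiff(REPORT_COLS, names(calls))
  if (length(missing_cols) > 0) {
    rlang::abort(paste("Missing columns:", paste(missing_cols, collapse = ", ")))
  }
  bad <- which(
    is.na(calls$position) | calls$position < 1 |
      (!calls$strand %in% c("+", "-")) |
      is.na(calls$count_methylated) | calls$count_methylated < 0 |
      is.na(calls$count_unmethylated) | calls$count_unmethylated < 0 |
      (!calls$context %in% c("CpG", "CHG", "CHH"))
  )
  if (!is.null(genome_length)) {
    bad <- union(bad, which(calls$position > genome_length))
  }
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "Malformed rows at line(s): %s",
      paste(sort(bad) + 1L, collapse = ", ")  # +1 for the header line
    ))
  }
  cov <- calls$count_methylated + calls$count_unmethylated
  calls$level <- ifelse(cov > 0, 100 * calls$count_methylated / cov, NA_real_)
  calls
}

#' Write a full simulated dataset as one report file per sample
#'
#' @param calls Long tibble of calls with `individual_id` and `area`.
#' @param dir Output directory (created if absent).
#' @param overwrite Passed to [write_cytosine_report()].
#' @return Tibble mapping `individual_id`, `area` to the file written.
#' @export
write_report_set <- function(calls, dir, overwrite = FALSE) {
  if (is.null(calls) || nrow(calls) == 0L) {
    rlang::abort("Refusing to write an empty call set.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- dplyr::distinct(calls, .data$individual_id, .data$area)
  samples$path <- file.path(
    dir, sprintf("%s_%s.cytosine_report.tsv", samples$individual_id, samples$area)
  )
  for (i in seq_len(nrow(samples))) {
    sub <- calls[calls$individual_id == samples$individual_id[i] &
                   calls$area == samples$area[i], ]
    write_cytosine_report(sub, samples$path[i], overwrite = overwrite)
  }
  samples
}

#' Read a directory of cytosine reports into one long call table
#'
#' @param paths Tibble from [write_report_set()] (or any tibble with
#'   `individual_id`, `area`, `path`).
#' @return Long call tibble matching [simulate_methylation()] output, with
#'   `level` attached.
#' @export
read_report_set <- function(paths) {
  dplyr::bind_rows(lapply(seq_len(nrow(paths)), function(i) {
    calls <- read_cytosine_report(paths$path[i])
    dplyr::bind_cols(
      tibble::tibble(individual_id = paths$individual_id[i], area = paths$area[i]),
      calls
    )
  }))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    individual_id = readr::col_character(),
    group = readr::col_character(),
    heroin = readr::col_logical(), ats = readr::col_logical(),
    ketamine = readr::col_logical(),
    age = readr::col_double(), alcohol = readr::col_logical(),
    pmi_class = readr::col_character(), batch = readr::col_character(),
    collector = readr::col_character(),
    cause_of_death = readr::col_character()
  ))
}

#' Write / read the cohort metadata table
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param path File path (TSV).
#' @param overwrite Refuse to clobber unless `TRUE`.
#' @return `path` invisibly (write); the cohort tibble (read).
#' @export
write_cohort <- function(cohort, path, overwrite = FALSE) {
  check_overwrite(path, overwrite)
  readr::write_tsv(cohort, path)
  invisible(path)
}

#' Write / read the ground-truth sidecar
#'
#' Serialises the planted effect sites and per-individual truth to JSON;
#' [read_truth()] restores an identical object.
#'
#' @param truth A `simulation_truth` from [generate_truth()].
#' @param path File path (JSON).
#' @param overwrite Refuse to clobber unless `TRUE`.
#' @return `path` invisibly (write); the truth object (read).
#' @export
write_truth <- function(truth, path, overwrite = FALSE) {
  stopifnot(inherits(truth, "simulation_truth"))
  check_overwrite(path, overwrite)
  jsonlite::write_json(unclass(truth), path, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    ba_sites = tibble::as_tibble(raw$ba_sites),
    age_sites = tibble::as_tibble(raw$age_sites),
    du_sites = tibble::as_tibble(raw$du_sites),
    individuals = tibble::as_tibble(raw$individuals)
  ), class = "simulation_truth")
}

#' Write / read a reference sequence as FASTA
#'
#' @param reference Sequence string.
#' @param path File path.
#' @param name Sequence header.
#' @param overwrite Refuse to clobber unless `TRUE`.
#' @return `path` invisibly (write); the sequence string (read).
#' @export
write_reference <- function(reference, path, name = "chrM_synthetic",
                            overwrite = FALSE) {
  check_overwrite(path, overwrite)
  seqinr::write.fasta(strsplit(reference, "")[[1]], names = name,
                      file.out = path)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  seq <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  toupper(as.character(seq[[1]]))
}
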