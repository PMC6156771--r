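#' Study-level evidence tables
#'
#' A study table holds one row per randomized comparison, with (possibly
#' missing) log hazard ratios and standard errors for overall survival (OS)
#' and progression-free survival (PFS). Missing outcomes are `NA` (empty
#' cells on disk), never sentinel numbers. Every row must report at least one
#' outcome, and a present estimate must come with a finite positive standard
#' error.
#'
#' @param study_id Character study labels.
#' @param ref,comp Treatment codes for the reference and comparator arm; the
#'   log hazard ratios are for `comp` relative to `ref`.
#' @param loghr_os,se_os,loghr_pfs,se_pfs Numeric estimates and standard
#'   errors; use `NA` for an unreported outcome.
#' @return A validated tibble with class `study_table`.
#' @examples
#' study_table(
#'   study_id = c("A", "B"), ref = "P", comp = "M+P",
#'   loghr_os = c(-0.1, -0.2), se_os = c(0.2, 0.25),
#'   loghr_pfs = c(-0.5, NA), se_pfs = c(0.2, NA)
#' )
#' @export
study_table <- function(study_id, ref, comp, loghr_os = NA_real_,
                        se_os = NA_real_, loghr_pfs = NA_real_,
                        se_pfs = NA_real_) {
  out <- tibble(
    study_id = as.character(study_id),
    ref = as.character(ref),
    comp = as.character(comp),
    loghr_os = as.numeric(loghr_os),
    se_os = as.numeric(se_os),
    loghr_pfs = as.numeric(loghr_pfs),
    se_pfs = as.numeric(se_pfs)
  )
  validate_study_table(out)
}

#' Validate a study table
#'
#' @param x A data frame with the study-table columns.
#' @return `x` as a tibble with class `study_table`, invisibly validated.
#' @export
validate_study_table <- function(x) {
  cols <- c("study_id", "ref", "comp", "loghr_os", "se_os", "loghr_pfs",
            "se_pfs")
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols)) {
    abort(paste0("Study table is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  x <- as_tibble(x)[cols]
  for (outc in c("os", "pfs")) {
    y <- x[[paste0("loghr_", outc)]]
    s <- x[[paste0("se_", outc)]]
    bad_pair <- which(is.na(y) != is.na(s))
    if (length(bad_pair)) {
      abort(paste0("Row ", bad_pair[1], ": `loghr_", outc, "` and `se_",
                   outc, "` must be present or absent together."))
    }
    bad_se <- which(!is.na(s) & (!is.finite(s) | s <= 0))
    if (length(bad_se)) {
      abort(paste0("Row ", bad_se[1], ", column `se_", outc,
                   "`: standard errors must be finite and positive."))
    }
    bad_y <- which(!is.na(y) & !is.finite(y))
    if (length(bad_y)) {
      abort(paste0("Row ", bad_y[1], ", column `loghr_", outc,
                   "`: estimates must be finite."))
    }
  }
  none <- which(is.na(x$loghr_os) & is.na(x$loghr_pfs))
  if (length(none)) {
    abort(paste0("Row ", none[1], " (", x$study_id[none[1]],
                 "): at least one of the OS/PFS estimates must be present."))
  }
  class(x) <- c("study_table", class(x))
  x
}

#' Read and write study tables as CSV
#'
#' The on-disk schema has columns `study_id, ref, comp, loghr_os, se_os,
#' loghr_pfs, se_pfs`; empty cells encode unreported outcomes. Malformed
#' numeric cells are reported with their row and column.
#'
#' @param path Path to a CSV file.
#' @return `read_study_table()` returns a validated `study_table` tibble
#'   (zero rows for a header-only file).
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      study_id = readr::col_character(),
      ref = readr::col_character(),
      comp = readr::col_character(),
      loghr_os = readr::col_double(),
      se_os = readr::col_double(),
      loghr_pfs = readr::col_double(),
      se_pfs = readr::col_double()
    ),
    progress = FALSE
  ))
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    colname <- names(raw)[probs$col[1]]
    abort(paste0("Malformed value in ", path, " at row ",
                 probs$row[1] - 1, " (", colname, "): expected ",
                 probs$expected[1], ", got '", probs$actual[1], "'."))
  }
  if (nrow(raw) == 0) {
    out <- raw
    class(out) <- c("study_table", class(out))
    return(out)
  }
  validate_study_table(raw)
}

#' @rdname read_study_table
#' @param x A `study_table` (or conforming data frame).
#' @return `write_study_table()` returns `path` invisibly.
#' @export
write_study_table <- function(x, path) {
  x <- validate_study_table(x)
  readr::write_csv(as_tibble(x), path, na = "")
  invisible(path)
}

#' Read a survival IPD table from CSV
#'
#' Individual patient data tables have columns `study_id, arm, time_months,
#' event` with `event` coded 1 for an observed event and 0 for right
#' censoring.
#'
#' @param path Path to a CSV file.
#' @return A tibble with the IPD schema.
#' @export
read_ipd_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      study_id = readr::col_character(),
      arm = readr::col_character(),
      time_months = readr::col_double(),
      event = readr::col_integer()
    ),
    progress = FALSE
  ))
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    abort(paste0("Malformed value in ", path, " at row ",
                 probs$row[1] - 1, " (", names(raw)[probs$col[1]], ")."))
  }
  validate_ipd(raw)
}

validate_ipd <- function(ipd) {
  cols <- c("study_id", "arm", "time_months", "event")
  if (!all(cols %in% names(ipd))) {
    abort(paste0("IPD table needs columns: ", paste(cols, collapse = ", "),
                 "."))
  }
  if (any(!is.finite(ipd$time_months) | ipd$time_months < 0)) {
    abort("`time_months` must be finite and non-negative.")
  }
  if (!all(ipd$event %in% c(0L, 1L))) {
    abort("`event` must be 0 (censored) or 1 (event).")
  }
  as_tibble(ipd)
}
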