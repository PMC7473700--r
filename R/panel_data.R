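#' Hospital-year panel
#'
#' A `hospital_panel` is a validated data frame of hospital-year records with
#' four input variables (beds, doctors, nurses, non-medical staff) and two
#' output variables (inpatient admissions, outpatient visits).  Panels may be
#' unbalanced: each hospital can contribute a different number of years, and a
#' combined pseudo-hospital (e.g. `"ALL"`) carrying system-wide totals for the
#' years where disaggregated figures are unavailable is treated as one more
#' unit with its own observation window.
#'
#' @param records data frame with columns `hospital_id`, `year`, `beds`,
#'   `doctors`, `nurses`, `nonmedical`, `inpatients`, `outpatients`.
#' @param study_window optional integer vector of length 2 giving the allowed
#'   calendar-year range; records outside it are rejected.
#'
#' @return An object of class `hospital_panel`: the record data frame with
#'   `hospital_id` as character, plus attributes `units` (distinct ids in
#'   order of first appearance) and `unbalanced` (logical).
#' @export
hospital_panel <- function(records, study_window = NULL) {
  required <- panel_columns()
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("panel schema error: missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- as.data.frame(records)[required]
  records$hospital_id <- as.character(records$hospital_id)
  if (nrow(records) == 0) {
    stop("panel schema error: no records", call. = FALSE)
  }

  count_vars <- panel_count_columns()
  for (v in c("year", count_vars)) {
    if (!is.numeric(records[[v]])) {
      stop("panel validation error: column '", v, "' is not numeric", call. = FALSE)
    }
  }
  for (v in count_vars) {
    bad <- which(!is.finite(records[[v]]) | records[[v]] <= 0)
    if (length(bad) > 0) {
      stop("panel validation error: non-positive or non-finite '", v,
           "' in row(s) ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (any(records$year != round(records$year))) {
    stop("panel validation error: non-integer year", call. = FALSE)
  }
  if (!is.null(study_window)) {
    outside <- which(records$year < study_window[1] | records$year > study_window[2])
    if (length(outside) > 0) {
      stop("panel validation error: year outside study window in row(s) ",
           paste(outside, collapse = ", "), call. = FALSE)
    }
  }
  # normalize storage so CSV round-trips compare identical
  records$year <- as.integer(records$year)
  for (v in count_vars) records[[v]] <- as.numeric(records[[v]])

  key <- paste(records$hospital_id, records$year, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("panel validation error: duplicate (hospital_id, year) in row(s) ",
         paste(dup, collapse = ", "), call. = FALSE)
  }

  units <- unique(records$hospital_id)
  t_i <- table(factor(records$hospital_id, levels = units))
  structure(records,
            units = units,
            unbalanced = length(unique(as.integer(t_i))) > 1,
            class = c("hospital_panel", "data.frame"))
}

panel_columns <- function() {
  c("hospital_id", "year", "beds", "doctors", "nurses", "nonmedical",
    "inpatients", "outpatients")
}

panel_count_columns <- function() {
  c("beds", "doctors", "nurses", "nonmedical", "inpatients", "outpatients")
}

#' Read a hospital-year panel from CSV
#'
#' Expects a comma-separated file with a header row (UTF-8, `.` decimal mark).
#' Column names can be remapped through `schema`, a named character vector
#' `c(<canonical> = <file column>)` for any columns whose file names differ
#' from the canonical `hospital_id`, `year`, `beds`, `doctors`, `nurses`,
#' `nonmedical`, `inpatients`, `outpatients`.
#'
#' @param path CSV file path.
#' @param schema optional named character vector remapping column names.
#' @param study_window optional allowed year range, passed to
#'   [hospital_panel()].
#' @return A [hospital_panel()] with one record per file row, row order
#'   preserved.
#' @export
load_panel <- function(path, schema = NULL, study_window = NULL) {
  if (!file.exists(path)) {
    stop("panel schema error: file not found: ", path, call. = FALSE)
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stop("panel schema error: ", conditionMessage(e), call. = FALSE)
  )
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(df)) {
        stop("panel schema error: mapped column '", src, "' not in file", call. = FALSE)
      }
      names(df)[names(df) == src] <- canonical
    }
  }
  hospital_panel(df, study_window = study_window)
}

#' Write a hospital-year panel to CSV
#'
#' Inverse of [load_panel()]: numeric content round-trips exactly for integer
#' counts.
#'
#' @param panel a [hospital_panel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "hospital_panel"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Descriptive statistics of a panel
#'
#' Per-variable mean, sample standard deviation (n - 1 denominator), minimum
#' and maximum over all records, in the layout of a descriptive-statistics
#' table.  With a single record the standard deviation is reported as `NA`
#' (undefined), not zero.
#'
#' @param panel a [hospital_panel()].
#' @return data frame with columns `variable`, `mean`, `sd`, `min`, `max`.
#' @export
summarize_panel <- function(panel) {
  stopifnot(inherits(panel, "hospital_panel"))
  vars <- panel_count_columns()
  out <- data.frame(
    variable = vars,
    mean = vapply(vars, function(v) mean(panel[[v]]), numeric(1)),
    sd   = vapply(vars, function(v) if (nrow(panel) < 2) NA_real_ else stats::sd(panel[[v]]),
                  numeric(1)),
    min  = vapply(vars, function(v) min(panel[[v]]), numeric(1)),
    max  = vapply(vars, function(v) max(panel[[v]]), numeric(1)),
    row.names = NULL
  )
  out
}

#' @export
print.hospital_panel <- function(x, ...) {
  units <- attr(x, "units")
  cat("Hospital-year panel: ", nrow(x), " records, ", length(units), " unit(s)",
      if (isTRUE(attr(x, "unbalanced"))) " (unbalanced)" else "", "\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}
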