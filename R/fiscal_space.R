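#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for monetary report cells, where R's
#' default banker's rounding would disagree with printed budget tables.
#'
#' @param x numeric.
#' @param digits decimal digits to keep.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Potential savings from an efficiency improvement
#'
#' Fiscal space created by raising hospital technical efficiency:
#' `Rev = (eff_target - eff_baseline) * G`, where `G` is the hospital
#' services budget.  The full-efficiency case sets `eff_target = 1`.
#' Returned unrounded; report cells use [round_half_up()] to the nearest
#' million.
#'
#' @param eff_baseline baseline mean technical efficiency, in `(0, 1]`.
#' @param eff_target target efficiency, in `(0, 1]`.
#' @param budget hospital services expenditure (e.g. MUR million).
#' @return Savings in budget units (negative with a warning when the target
#'   is below baseline — a disinvestment scenario, not an error).
#' @export
savings <- function(eff_baseline, eff_target, budget) {
  stopifnot(eff_baseline > 0, eff_baseline <= 1,
            eff_target > 0, eff_target <= 1, budget > 0)
  out <- (eff_target - eff_baseline) * budget
  if (eff_target < eff_baseline) {
    warning("disinvestment scenario: target efficiency below baseline", call. = FALSE)
  }
  out
}

#' Cross-product grid of savings scenarios
#'
#' Builds the full baselines x targets x fiscal-year-budgets grid of
#' [savings()] cells.  Monetary cells are rounded half-up to the nearest
#' million; the unrounded value is kept in `savings_raw`.  When a matching
#' General Government Health Expenditure (GGHE) level is supplied for a year,
#' the savings share of GGHE is added as a percentage rounded to one
#' decimal.
#'
#' @param baselines numeric vector of baseline efficiencies.
#' @param targets numeric vector of target efficiencies.
#' @param budgets named numeric vector of budgets, names are fiscal-year
#'   labels (e.g. `c("FY2021-22" = 10555)`).
#' @param gghe optional named numeric vector of GGHE levels by the same
#'   fiscal-year labels.
#' @param years optional subset of fiscal-year labels to use; all budget
#'   years by default.  A requested year missing from `budgets` is an error.
#' @return A `scenario_grid` data frame with columns `fiscal_year`, `budget`,
#'   `eff_baseline`, `eff_target`, `savings` (rounded MUR million),
#'   `savings_raw`, and `share_of_gghe` when `gghe` is given.
#' @export
scenario_grid <- function(baselines, targets, budgets, gghe = NULL, years = NULL) {
  stopifnot(length(baselines) > 0, length(targets) > 0, length(budgets) > 0,
            !is.null(names(budgets)))
  if (is.null(years)) years <- names(budgets)
  missing_years <- setdiff(years, names(budgets))
  if (length(missing_years) > 0) {
    stop("no budget for fiscal year(s): ", paste(missing_years, collapse = ", "),
         call. = FALSE)
  }
  grid <- expand.grid(eff_target = targets, eff_baseline = baselines,
                      fiscal_year = years, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("fiscal_year", "eff_baseline", "eff_target")]
  grid$budget <- unname(budgets[grid$fiscal_year])
  grid$savings_raw <- (grid$eff_target - grid$eff_baseline) * grid$budget
  grid$savings <- round_half_up(grid$savings_raw)
  if (!is.null(gghe)) {
    g <- unname(gghe[grid$fiscal_year])
    grid$share_of_gghe <- round_half_up(100 * grid$savings_raw / g, 1)
  }
  structure(grid, class = c("scenario_grid", "data.frame"))
}

#' Write a savings scenario grid to CSV
#'
#' @param grid a [scenario_grid()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scenarios <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
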