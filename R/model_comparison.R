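#' Likelihood-ratio test of nested frontier specifications
#'
#' Tests the joint null that the parameters restricted away in the smaller
#' model are zero (e.g. all second-order translog terms), using the standard
#' chi-square reference: `LR = 2 (lnL_full - lnL_restricted)` against
#' chi-square with `df` degrees of freedom.  For the Cobb-Douglas vs translog
#' comparison with four inputs, `df = 10` (6 interactions + 4 half-squares).
#' The mixed chi-square adjustment that applies when a variance parameter is
#' pinned at its boundary is not relevant here (both models share the same
#' variance block) and is not implemented.
#'
#' @param loglik_restricted log-likelihood of the nested (smaller) model.
#' @param loglik_full log-likelihood of the full model.
#' @param df number of restricted parameters (`>= 1`).
#' @param tol tolerance for a slightly negative statistic arising from
#'   imperfect optimization; a larger negative value is an error.
#' @return An object of class `frontier_test` (a list with `statistic`, `df`,
#'   `p_value`, `method`).
#' @export
lr_test <- function(loglik_restricted, loglik_full, df, tol = 1e-6) {
  stopifnot(df >= 1)
  statistic <- 2 * (loglik_full - loglik_restricted)
  if (statistic < -tol) {
    stop("negative likelihood-ratio statistic (", format(statistic),
         "): models not nested or optimization failed", call. = FALSE)
  }
  statistic <- max(statistic, 0)
  structure(
    list(statistic = statistic, df = as.integer(df),
         p_value = stats::pchisq(statistic, df = df, lower.tail = FALSE),
         ci = NULL, method = "likelihood-ratio test (chi-square)"),
    class = "frontier_test"
  )
}

#' Paired t-test between two efficiency-score series
#'
#' Compares matched unit-year technical-efficiency scores from two
#' specifications (difference taken as `b - a`), with the two-sided p-value
#' and a confidence interval on the mean difference.
#'
#' @param scores_a,scores_b numeric score series of equal length `>= 2`,
#'   matched element-wise (same unit-years).
#' @param conf_level confidence level for the interval.
#' @return A `frontier_test` object with `statistic` (t), `df`, `p_value`,
#'   `ci` and `estimate` (mean difference `b - a`).
#' @export
paired_t <- function(scores_a, scores_b, conf_level = 0.95) {
  if (length(scores_a) != length(scores_b)) {
    stop("pairing error: series lengths differ (", length(scores_a), " vs ",
         length(scores_b), ")", call. = FALSE)
  }
  if (length(scores_a) < 2) stop("at least 2 pairs are required", call. = FALSE)
  d <- scores_b - scores_a
  if (stats::sd(d) == 0) {
    if (mean(d) != 0) {
      stop("degenerate case: zero-variance differences with nonzero mean", call. = FALSE)
    }
    # identical series: no evidence of any difference
    return(structure(
      list(statistic = 0, df = length(d) - 1L, p_value = 1, ci = c(0, 0),
           estimate = 0, method = "paired t-test"),
      class = "frontier_test"))
  }
  tt <- stats::t.test(scores_b, scores_a, paired = TRUE, conf.level = conf_level)
  structure(
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, ci = as.numeric(tt$conf.int),
         estimate = unname(tt$estimate), method = "paired t-test"),
    class = "frontier_test"
  )
}

#' @export
print.frontier_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 5),
      ", df = ", format(x$df), ", p = ", format.pval(x$p_value, digits = 4),
      sep = "")
  if (!is.null(x$ci)) {
    cat(sprintf(", CI [%.4g, %.4g]", x$ci[1], x$ci[2]))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.frontier_test <- function(x, ...) {
  data.frame(method = x$method, statistic = x$statistic, df = x$df,
             p_value = x$p_value,
             ci_lower = if (is.null(x$ci)) NA_real_ else x$ci[1],
             ci_upper = if (is.null(x$ci)) NA_real_ else x$ci[2],
             row.names = NULL)
}
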