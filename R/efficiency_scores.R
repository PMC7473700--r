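#' Battese-Coelli technical-efficiency scores
#'
#' Point efficiency per unit under the time-invariant composed-error model:
#' `TE_i = E[exp(-u_i) | e_i1, ..., e_iT]`, the conditional expectation of
#' `exp(-u_i)` under the truncated-normal posterior of the unit's
#' inefficiency draw given its residual vector.  With posterior location
#' `mu_i* = (mu sigma_v2 - sigma_u2 sum_t e_it) / (sigma_v2 + T_i sigma_u2)`
#' and scale `sigma_*^2 = sigma_u2 sigma_v2 / (sigma_v2 + T_i sigma_u2)`,
#' the closed form is
#' `TE_i = exp(-mu_i* + sigma_*^2 / 2) * Phi(mu_i*/sigma_* - sigma_*) / Phi(mu_i*/sigma_*)`.
#' The model is time-invariant, so the unit score is broadcast to each of the
#' unit's years for reporting.
#'
#' @param fit a converged [fit_frontier()] result.
#' @param design the [build_design()] object the fit was estimated on.
#' @return An object of classes `efficiency_table`/`data.frame` with columns
#'   `unit`, `year`, `score` (one row per unit-year, scores in `(0, 1]`) and
#'   attributes `spec_form` and `unit_scores` (named per-unit vector).
#' @export
bc_efficiency <- function(fit, design) {
  stopifnot(inherits(fit, "frontier_fit"), inherits(design, "frontier_design"))
  if (!isTRUE(fit$converged)) {
    stop("efficiency scores refused: frontier fit did not converge", call. = FALSE)
  }
  if (!identical(fit$spec$form, design$spec$form) ||
      length(fit$beta) != ncol(design$X)) {
    stop("design does not match the fitted specification", call. = FALSE)
  }
  p <- fit$variance$sigma_u2
  q <- fit$variance$sigma_v2
  mu <- fit$variance$mu
  e <- design$response - drop(design$X %*% fit$beta)
  us <- unit_stats(e, design$unit)
  units <- levels(us$f)

  if (p == 0) {
    scores <- rep(exp(-max(mu, 0)), length(units))
  } else {
    D <- q + us$T_i * p
    mu_star <- (mu * q - p * us$S1) / D
    s_star <- sqrt(p * q / D)
    # log-space evaluation of exp(-mu* + s*^2/2) Phi(mu*/s* - s*) / Phi(mu*/s*)
    log_te <- -mu_star + s_star^2 / 2 +
      stats::pnorm(mu_star / s_star - s_star, log.p = TRUE) -
      stats::pnorm(mu_star / s_star, log.p = TRUE)
    scores <- exp(log_te)
  }

  over <- scores - 1
  if (any(over > 1e-12) || any(scores <= 0)) {
    stop("internal consistency error: efficiency score outside (0, 1]", call. = FALSE)
  }
  scores <- pmin(scores, 1)

  tab <- data.frame(unit = design$unit, year = design$year,
                    score = scores[as.integer(us$f)], row.names = NULL)
  structure(tab, spec_form = fit$spec$form,
            unit_scores = stats::setNames(scores, units),
            class = c("efficiency_table", "data.frame"))
}

#' Summarize technical-efficiency scores over a year window
#'
#' Mean and sample standard deviation of the unit-year scores whose years
#' fall in `window`, with a t-interval on the mean.
#'
#' @param table an [bc_efficiency()] result.
#' @param window integer vector of length 2 (inclusive year range); `NULL`
#'   uses all years.
#' @param ci_level confidence level for the t-interval.
#' @return data frame (class `efficiency_summary`) with columns `period`,
#'   `n`, `mean`, `sd`, `ci_lower`, `ci_upper`.
#' @export
summarize_efficiency <- function(table, window = NULL, ci_level = 0.95) {
  stopifnot(inherits(table, "efficiency_table"))
  if (is.null(window)) window <- range(table$year)
  keep <- table$year >= window[1] & table$year <= window[2]
  if (!any(keep)) stop("empty year window ", window[1], "-", window[2], call. = FALSE)
  s <- table$score[keep]
  n <- length(s)
  m <- mean(s)
  sdev <- if (n > 1) stats::sd(s) else NA_real_
  half <- if (n > 1 && sdev > 0) {
    stats::qt(1 - (1 - ci_level) / 2, df = n - 1) * sdev / sqrt(n)
  } else 0
  out <- data.frame(period = paste0(window[1], "-", window[2]), n = n,
                    mean = m, sd = sdev, ci_lower = m - half, ci_upper = m + half,
                    row.names = NULL)
  class(out) <- c("efficiency_summary", "data.frame")
  out
}

#' Write an efficiency table to CSV
#'
#' @param table an [bc_efficiency()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_efficiency <- function(table, path) {
  df <- data.frame(as.data.frame(table), spec = attr(table, "spec_form"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
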