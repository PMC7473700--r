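#' Variance parameterization of the composed error
#'
#' The composed error of the frontier model is `e_it = v_it - u_i` with noise
#' `v_it ~ N(0, sigma_v2)` and time-invariant inefficiency
#' `u_i ~ N(mu, sigma_u2)` truncated at zero.  Estimation and reporting use
#' the reparameterization `sigma2 = sigma_u2 + sigma_v2` and
#' `gamma = sigma_u2 / sigma2` (share of composed-error variance due to
#' inefficiency), with unconstrained coordinates `ln(sigma2)` and the inverse
#' logit transform `ilgt_gamma = ln(gamma / (1 - gamma))`.
#'
#' @param sigma_u2 inefficiency variance, `>= 0`.
#' @param sigma_v2 noise variance, `> 0`.
#' @param mu location of the truncated-normal inefficiency distribution.
#' @return An object of class `variance_params` with fields `sigma_u2`,
#'   `sigma_v2`, `sigma2`, `gamma`, `mu`, `ln_sigma2`, `ilgt_gamma`.
#'   `ilgt_gamma` is `-Inf`/`Inf` at the `gamma = 0`/`1` boundaries.
#' @export
param_transforms <- function(sigma_u2, sigma_v2, mu = 0) {
  stopifnot(is.finite(sigma_u2), is.finite(sigma_v2), is.finite(mu))
  if (sigma_u2 < 0) stop("sigma_u2 must be nonnegative", call. = FALSE)
  if (sigma_v2 <= 0) stop("sigma_v2 must be positive", call. = FALSE)
  sigma2 <- sigma_u2 + sigma_v2
  gamma <- sigma_u2 / sigma2
  structure(
    list(sigma_u2 = sigma_u2, sigma_v2 = sigma_v2, sigma2 = sigma2,
         gamma = gamma, mu = mu, ln_sigma2 = log(sigma2),
         ilgt_gamma = if (gamma <= 0) -Inf else if (gamma >= 1) Inf
                      else log(gamma / (1 - gamma))),
    class = "variance_params"
  )
}

#' Variance parameters from unconstrained coordinates
#'
#' Inverse of the working transform used by the optimizer:
#' `sigma2 = exp(ln_sigma2)`, `gamma = plogis(ilgt_gamma)`.
#'
#' @param ln_sigma2,ilgt_gamma,mu unconstrained coordinates.
#' @return A `variance_params` object (see [param_transforms()]).
#' @export
variance_from_working <- function(ln_sigma2, ilgt_gamma, mu) {
  sigma2 <- exp(ln_sigma2)
  gamma <- stats::plogis(ilgt_gamma)
  param_transforms(sigma_u2 = gamma * sigma2, sigma_v2 = (1 - gamma) * sigma2,
                   mu = mu)
}

#' @export
print.variance_params <- function(x, ...) {
  cat(sprintf("sigma_u2 = %.6g, sigma_v2 = %.6g, sigma2 = %.6g\n",
              x$sigma_u2, x$sigma_v2, x$sigma2))
  cat(sprintf("gamma = %.6g (ilgt = %.6g), mu = %.6g\n",
              x$gamma, x$ilgt_gamma, x$mu))
  invisible(x)
}

# log(phi(z)/Phi(z)), computed in log space for stability
inv_mills <- function(z) exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))

# Per-unit sufficient statistics of the residuals.
unit_stats <- function(e, unit) {
  f <- factor(unit, levels = unique(unit))
  list(S1 = as.vector(rowsum(e, f)),
       S2 = as.vector(rowsum(e^2, f)),
       T_i = as.vector(table(f)),
       f = f)
}

# Marginal log-likelihood contributions per unit, closed form.
# e = v - u, u ~ N(mu, p) truncated at 0, v ~ N(0, q) iid.
#
# Evaluated in the scaled-location parameterization m = mu / sqrt(p) with
# A = m q - sqrt(p) S1, which combines the posterior and prior quadratic
# terms algebraically: the naive form subtracts two O(mu^2/p) quantities and
# loses all precision as p -> 0, whereas here the p -> 0 limit is exactly
# the pooled Gaussian log-likelihood.
bc_unit_loglik <- function(S1, S2, T_i, p, q, mu) {
  if (p == 0) stop("bc_unit_loglik requires sigma_u2 > 0; use the pooled limit")
  sp <- sqrt(p)
  m <- mu / sp
  D <- q + T_i * p
  A <- m * q - sp * S1
  zA <- A / sqrt(q * D)
  -T_i / 2 * log(2 * pi) - (T_i - 1) / 2 * log(q) - 0.5 * log(D) -
    S2 / (2 * q) + A^2 / (2 * q * D) - m^2 / 2 +
    stats::pnorm(zA, log.p = TRUE) - stats::pnorm(m, log.p = TRUE)
}

# Gradient building blocks in (beta, p, q, m) coordinates, per the same
# stable algebra as bc_unit_loglik.  Returns the summed partials.
bc_core_grad <- function(beta, p, q, m, design) {
  e <- design$response - drop(design$X %*% beta)
  us <- unit_stats(e, design$unit)
  S1 <- us$S1; S2 <- us$S2; T_i <- us$T_i
  sp <- sqrt(p)
  D <- q + T_i * p
  A <- m * q - sp * S1
  qD <- q * D
  zA <- A / sqrt(qD)
  h <- inv_mills(zA)
  hm <- inv_mills(m)

  # beta: sum_t e_it x_it / q + (A sqrt(p)/(qD) + h sqrt(p)/sqrt(qD)) sum_t x_it
  c_i <- A * sp / qD + h * sp / sqrt(qD)
  row_c <- c_i[as.integer(us$f)]
  g_beta <- drop(crossprod(design$X, e / q + row_c))

  dA_dp <- -S1 / (2 * sp)
  gp <- sum(-T_i / (2 * D) + A * dA_dp / qD - A^2 * T_i / (2 * q * D^2) +
              h * (dA_dp / sqrt(qD) - zA * T_i / (2 * D)))
  gq <- sum(-(T_i - 1) / (2 * q) - 1 / (2 * D) + S2 / (2 * q^2) +
              A * m / qD - A^2 / (2 * qD) * (1 / q + 1 / D) +
              h * (m / sqrt(qD) - zA * (1 / q + 1 / D) / 2))
  gm <- sum(A / D - m + h * sqrt(q / D)) - length(S1) * hm

  list(beta = g_beta, p = gp, q = gq, m = gm)
}

#' Composed-error panel log-likelihood
#'
#' Exact marginal log-likelihood of the normal-truncated-normal stochastic
#' frontier with time-invariant inefficiency: for each unit the inefficiency
#' draw `u_i` is integrated out of the joint density of that unit's residuals
#' `e_it = y_it - x_it' beta` in closed form, evaluated in log space.
#' At `sigma_u2 = 0` the model degenerates to pooled Gaussian regression
#' (with the inefficiency point mass `max(mu, 0)` shifting the residuals).
#'
#' @param beta coefficient vector, in design column order (constant first).
#' @param variance a [param_transforms()] object.
#' @param design a [build_design()] result.
#' @param by_unit if `TRUE`, return the per-unit contribution vector instead
#'   of the sum.
#' @return Log-likelihood value (or per-unit vector).
#' @export
composed_loglik <- function(beta, variance, design, by_unit = FALSE) {
  stopifnot(inherits(design, "frontier_design"))
  if (!inherits(variance, "variance_params")) stop("variance must be a variance_params object")
  if (variance$sigma_v2 <= 0) stop("sigma_v2 must be positive", call. = FALSE)
  if (length(beta) != ncol(design$X)) stop("beta length does not match design columns")
  e <- design$response - drop(design$X %*% beta)
  if (any(!is.finite(e))) stop("non-finite residual", call. = FALSE)

  if (variance$sigma_u2 == 0) {
    u0 <- max(variance$mu, 0)
    ll <- stats::dnorm(e + u0, mean = 0, sd = sqrt(variance$sigma_v2), log = TRUE)
    if (by_unit) {
      us <- unit_stats(e, design$unit)
      return(as.vector(rowsum(ll, us$f)))
    }
    return(sum(ll))
  }

  us <- unit_stats(e, design$unit)
  ll_i <- bc_unit_loglik(us$S1, us$S2, us$T_i,
                         p = variance$sigma_u2, q = variance$sigma_v2,
                         mu = variance$mu)
  if (by_unit) ll_i else sum(ll_i)
}

# Analytic gradient of the log-likelihood in working coordinates
# (beta, ln_sigma2, ilgt_gamma, mu).  Validated against a numerical gradient
# in the test suite.
composed_loglik_grad <- function(beta, variance, design) {
  p <- variance$sigma_u2; q <- variance$sigma_v2; mu <- variance$mu
  m <- mu / sqrt(p)
  g <- bc_core_grad(beta, p, q, m, design)
  # in (p, q, mu) coordinates m depends on both mu and p
  dll_dmu <- g$m / sqrt(p)
  dll_dp <- g$p - g$m * m / (2 * p)
  sigma2 <- variance$sigma2
  gam <- variance$gamma
  g_a <- p * dll_dp + q * g$q
  g_g <- sigma2 * gam * (1 - gam) * (dll_dp - g$q)
  c(g$beta, ln_sigma2 = g_a, ilgt_gamma = g_g, mu = dll_dmu)
}

#' Optimizer settings for [fit_frontier()]
#'
#' @param n_starts number of optimizer starts; the first is the
#'   corrected-OLS start, the rest are jittered copies of it (composed-error
#'   likelihoods can be multi-modal near the gamma boundary).
#' @param jitter_seed RNG seed for the start jitter.
#' @param jitter_sd relative scale of the jitter.
#' @param maxit,reltol passed to [stats::optim()] (BFGS).
#' @param gamma_start,mu_start starting values for the variance block
#'   (`mu_start` is in the scaled coordinate `m = mu / sigma_u`).
#' @return list of settings.
#' @export
frontier_control <- function(n_starts = 5, jitter_seed = 42, jitter_sd = 0.3,
                             maxit = 2000, reltol = 1e-12,
                             gamma_start = 0.5, mu_start = 0) {
  list(n_starts = n_starts, jitter_seed = jitter_seed, jitter_sd = jitter_sd,
       maxit = maxit, reltol = reltol, gamma_start = gamma_start,
       mu_start = mu_start)
}

# Run code with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fit a panel stochastic frontier by maximum likelihood
#'
#' Maximizes the composed-error log-likelihood of [composed_loglik()] over
#' the unconstrained coordinates `(beta, ln sigma2, ilgt gamma, m)`, where
#' `m = mu / sigma_u` is the scaled truncation location (numerically smooth
#' as `gamma -> 0`, where `mu` itself is unidentified), with BFGS (analytic
#' gradient) from
#' corrected-OLS starting values: OLS slopes, `sigma2` at the OLS residual
#' variance, `gamma = 0.5`, `mu = 0`, plus jittered multi-starts.  Standard
#' errors come from the inverse observed information (numerical Hessian at
#' the optimum); a Wald chi-square statistic tests joint significance of all
#' slope coefficients.
#'
#' @param design a [build_design()] result with at least 2 units.
#' @param control a [frontier_control()] list.
#' @return An object of class `frontier_fit` with elements `beta` (named),
#'   `variance` ([param_transforms()] object), `loglik`, `wald_chi2`,
#'   `wald_df`, `wald_p`, `covariance` (working coordinates, columns
#'   `beta..., ln_sigma2, ilgt_gamma, m`), `se` (working coordinates),
#'   `variance_se` (delta-method SEs for `sigma2`, `gamma`, `sigma_u2`,
#'   `sigma_v2`, `mu`), `converged`, `n_obs`, `n_units`, `spec`,
#'   `optimizer_trace`.
#' @export
fit_frontier <- function(design, control = frontier_control()) {
  stopifnot(inherits(design, "frontier_design"))
  X <- design$X
  y <- design$response
  n <- length(y)
  k <- ncol(X)
  n_units <- length(unique(design$unit))
  if (n_units < 2) stop("at least 2 units are required", call. = FALSE)

  ols <- stats::lm.fit(X, y)
  beta_ols <- ols$coefficients
  rank_deficient <- ols$rank < k
  # collinear columns (e.g. a near-constant output-ratio regressor) get a
  # zero start; the likelihood itself is still well defined there
  beta_ols[is.na(beta_ols)] <- 0
  res_var <- sum(ols$residuals^2) / max(n - ols$rank, 1)

  # Noise-free frontier: all observations exactly on the fitted plane.
  if (res_var < 1e-14) {
    variance <- param_transforms(sigma_u2 = 0, sigma_v2 = 1e-12, mu = 0)
    fit <- structure(
      list(beta = stats::setNames(beta_ols, colnames(X)), variance = variance,
           loglik = Inf, wald_chi2 = NA_real_, wald_df = k - 1L,
           wald_p = NA_real_, covariance = NULL, se = NULL,
           variance_se = NULL, converged = TRUE, n_obs = n,
           n_units = n_units, spec = design$spec,
           optimizer_trace = list(note = "degenerate noise-free fit (OLS exact)")),
      class = "frontier_fit")
    return(fit)
  }

  # Working coordinates: (beta, ln sigma2, ilgt gamma, m) with m = mu/sigma_u.
  # The scaled location keeps the likelihood numerically smooth as gamma -> 0,
  # where mu itself is unidentified.
  theta0 <- c(beta_ols, log(res_var), stats::qlogis(control$gamma_start),
              control$mu_start)
  idx_beta <- seq_len(k)
  unpack <- function(theta) {
    sigma2 <- exp(theta[k + 1])
    gam <- stats::plogis(theta[k + 2])
    p <- gam * sigma2
    list(beta = theta[idx_beta],
         variance = param_transforms(p, (1 - gam) * sigma2,
                                     mu = theta[k + 3] * sqrt(p)))
  }
  negll <- function(theta) {
    par <- tryCatch(unpack(theta), error = function(e) NULL)
    if (is.null(par)) return(1e10)
    v <- tryCatch(composed_loglik(par$beta, par$variance, design),
                  error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else -v
  }
  neggr <- function(theta) {
    par <- tryCatch(unpack(theta), error = function(e) NULL)
    if (is.null(par)) return(rep(0, length(theta)))
    g <- tryCatch({
      v <- par$variance
      gc <- bc_core_grad(par$beta, v$sigma_u2, v$sigma_v2, theta[k + 3], design)
      c(gc$beta,
        v$sigma_u2 * gc$p + v$sigma_v2 * gc$q,
        v$sigma2 * v$gamma * (1 - v$gamma) * (gc$p - gc$q),
        gc$m)
    }, error = function(e) rep(NA_real_, length(theta)))
    if (any(!is.finite(g))) rep(0, length(theta)) else -g
  }

  starts <- with_local_seed(control$jitter_seed, {
    lapply(seq_len(control$n_starts), function(s) {
      if (s == 1) theta0
      else theta0 + stats::rnorm(length(theta0)) * control$jitter_sd *
        pmax(abs(theta0), 0.5)
    })
  })

  runs <- lapply(starts, function(th) {
    tryCatch(
      stats::optim(th, fn = negll, gr = neggr, method = "BFGS",
                   control = list(maxit = control$maxit, reltol = control$reltol)),
      error = function(e) list(value = Inf, convergence = 99L,
                               message = conditionMessage(e))
    )
  })
  values <- vapply(runs, function(r) r$value, numeric(1))
  best <- runs[[which.min(values)]]
  converged <- is.finite(best$value) && best$value < 1e9 &&
    identical(as.integer(best$convergence), 0L)

  theta_hat <- best$par
  par_hat <- unpack(theta_hat)
  loglik <- -best$value

  trace <- list(start_values = -values,
                best_start = which.min(values),
                optim_convergence = best$convergence,
                warnings = if (rank_deficient)
                  sprintf("design rank %d < %d columns: collinear regressors, coefficients not separately identified", ols$rank, k)
                else character(0))
  if (par_hat$variance$gamma > 0.9999 || par_hat$variance$gamma < 1e-4) {
    trace$warnings <- c(trace$warnings,
                        sprintf("gamma pinned near boundary (%.6g)", par_hat$variance$gamma))
  }

  covariance <- NULL; se <- NULL; variance_se <- NULL
  wald <- c(chi2 = NA_real_, p = NA_real_)
  if (converged) {
    H <- pracma::hessian(negll, theta_hat)
    covariance <- tryCatch(solve(H), error = function(e) pracma::pinv(H))
    covariance <- (covariance + t(covariance)) / 2
    wnames <- c(colnames(X), "ln_sigma2", "ilgt_gamma", "m")
    dimnames(covariance) <- list(wnames, wnames)
    dvar <- diag(covariance)
    if (any(dvar < 0)) {
      trace$warnings <- c(trace$warnings, "observed information not positive definite")
      dvar[dvar < 0] <- NA_real_
    }
    se <- sqrt(dvar)

    # delta method for derived variance-block quantities
    s2 <- par_hat$variance$sigma2
    gam <- par_hat$variance$gamma
    mu_hat <- par_hat$variance$mu
    Vagm <- covariance[c("ln_sigma2", "ilgt_gamma", "m"),
                       c("ln_sigma2", "ilgt_gamma", "m")]
    dgam <- gam * (1 - gam)
    J <- rbind(sigma2 = c(s2, 0, 0),
               gamma = c(0, dgam, 0),
               sigma_u2 = c(gam * s2, s2 * dgam, 0),
               sigma_v2 = c((1 - gam) * s2, -s2 * dgam, 0),
               mu = c(mu_hat / 2, mu_hat * (1 - gam) / 2, sqrt(gam * s2)))
    vs <- diag(J %*% Vagm %*% t(J))
    variance_se <- stats::setNames(sqrt(pmax(vs, 0)), rownames(J))

    slope_idx <- 2:k
    Vb <- covariance[slope_idx, slope_idx, drop = FALSE]
    b <- par_hat$beta[slope_idx]
    wald_chi2 <- tryCatch(drop(t(b) %*% solve(Vb, b)), error = function(e) NA_real_)
    if (is.finite(wald_chi2) && wald_chi2 < 0) {
      # only possible when the information matrix is not positive definite
      wald_chi2 <- NA_real_
    }
    wald <- c(chi2 = wald_chi2,
              p = if (is.finite(wald_chi2)) stats::pchisq(wald_chi2, df = k - 1, lower.tail = FALSE)
                  else NA_real_)
  }

  structure(
    list(beta = stats::setNames(par_hat$beta, colnames(X)),
         variance = par_hat$variance, loglik = loglik,
         wald_chi2 = unname(wald["chi2"]), wald_df = k - 1L,
         wald_p = unname(wald["p"]), covariance = covariance, se = se,
         variance_se = variance_se, converged = converged, n_obs = n,
         n_units = n_units, spec = design$spec, optimizer_trace = trace),
    class = "frontier_fit"
  )
}

#' @export
logLik.frontier_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) + 3L,
            nobs = object$n_obs, class = "logLik")
}

#' @export
coef.frontier_fit <- function(object, ...) object$beta

#' @export
vcov.frontier_fit <- function(object, ...) object$covariance

#' Coefficient table of a frontier fit
#'
#' Estimates, standard errors, z statistics and two-sided p-values for the
#' frontier coefficients and the variance block, in the layout of a
#' maximum-likelihood frontier report (variance rows appended under the
#' slopes; explicit p-values rather than significance stars).
#'
#' @param fit a [fit_frontier()] result.
#' @return data frame with columns `parameter`, `estimate`, `se`, `z`, `p`.
#' @export
fit_table <- function(fit) {
  stopifnot(inherits(fit, "frontier_fit"))
  v <- fit$variance
  params <- c(names(fit$beta), "sigma_u2", "sigma_v2", "sigma2", "ln_sigma2",
              "gamma", "ilgt_gamma", "mu")
  est <- c(fit$beta, v$sigma_u2, v$sigma_v2, v$sigma2, v$ln_sigma2,
           v$gamma, v$ilgt_gamma, v$mu)
  se <- rep(NA_real_, length(est))
  if (!is.null(fit$se)) {
    k <- length(fit$beta)
    se[seq_len(k)] <- fit$se[seq_len(k)]
    se[k + 1] <- fit$variance_se["sigma_u2"]
    se[k + 2] <- fit$variance_se["sigma_v2"]
    se[k + 3] <- fit$variance_se["sigma2"]
    se[k + 4] <- fit$se["ln_sigma2"]
    se[k + 5] <- fit$variance_se["gamma"]
    se[k + 6] <- fit$se["ilgt_gamma"]
    se[k + 7] <- fit$variance_se["mu"]
  }
  z <- est / se
  data.frame(parameter = params, estimate = unname(est), se = unname(se),
             z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
             row.names = NULL)
}

#' @export
print.frontier_fit <- function(x, digits = 4, ...) {
  cat("Stochastic frontier fit (", x$spec$form, "), n = ", x$n_obs,
      " obs in ", x$n_units, " unit(s)\n", sep = "")
  if (!x$converged) cat("** optimizer did not converge **\n")
  tab <- fit_table(x)
  tab[, -1] <- lapply(tab[, -1], signif, digits = digits)
  print(tab, row.names = FALSE)
  cat(sprintf("Log likelihood: %.3f   Wald chi2(%d): %.2f (p = %.3g)\n",
              x$loglik, x$wald_df, x$wald_chi2, x$wald_p))
  if (length(x$optimizer_trace$warnings) > 0) {
    cat("Warnings:", paste(x$optimizer_trace$warnings, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Serialize a frontier fit to JSON
#'
#' @param fit a [fit_frontier()] result.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
fit_report_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "frontier_fit"))
  obj <- list(
    form = fit$spec$form,
    coefficients = as.list(fit$beta),
    variance = fit$variance[c("sigma_u2", "sigma_v2", "sigma2", "gamma", "mu",
                              "ln_sigma2", "ilgt_gamma")],
    loglik = fit$loglik, wald_chi2 = fit$wald_chi2, wald_df = fit$wald_df,
    wald_p = fit$wald_p, converged = fit$converged, n_obs = fit$n_obs,
    n_units = fit$n_units
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
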