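test_that("variance transforms reproduce the gamma/sigma2 identities", {
  v <- param_transforms(0.018, 0.004, mu = 0.045)
  expect_equal(v$sigma2, 0.022)
  expect_equal(v$gamma, 0.018 / 0.022)
  expect_equal(v$ilgt_gamma, log(v$gamma / (1 - v$gamma)))

  # logit symmetry and worked inverse-logit value
  expect_equal(param_transforms(0.5, 0.5)$ilgt_gamma, 0)
  g <- 0.79
  v79 <- param_transforms(g * 0.022, (1 - g) * 0.022)
  expect_equal(v79$ilgt_gamma, log(0.79 / 0.21))

  # round trip through the unconstrained coordinates
  back <- variance_from_working(v$ln_sigma2, v$ilgt_gamma, v$mu)
  expect_equal(back$sigma_u2, v$sigma_u2, tolerance = 1e-12)
  expect_equal(back$sigma_v2, v$sigma_v2, tolerance = 1e-12)

  # boundary: gamma exactly 0 has an infinite inverse logit marker
  expect_equal(param_transforms(0, 1)$ilgt_gamma, -Inf)
  expect_error(param_transforms(0.01, 0), "positive")
  expect_error(param_transforms(-0.01, 0.1), "nonnegative")
})

test_that("composed likelihood matches the quadrature oracle on a toy panel", {
  d <- toy_design(T_i = 2, n_units = 2)
  beta <- toy_beta(d)
  e <- d$response - drop(d$X %*% beta)
  for (pars in list(c(0.02, 0.005, 0.05), c(0.001, 0.01, -0.02), c(0.05, 0.002, 0))) {
    v <- param_transforms(pars[1], pars[2], pars[3])
    mine <- composed_loglik(beta, v, d, by_unit = TRUE)
    f <- factor(d$unit, levels = unique(d$unit))
    oracle <- vapply(split(e, f), quad_loglik_unit, numeric(1),
                     sigma_u2 = pars[1], sigma_v2 = pars[2], mu = pars[3])
    expect_equal(mine, unname(oracle), tolerance = 1e-6)
  }
})

test_that("at gamma = 0 the likelihood is the pooled Gaussian log-likelihood", {
  d <- toy_design(T_i = 3)
  beta <- toy_beta(d)
  v <- param_transforms(0, 0.01, mu = 0)
  e <- d$response - drop(d$X %*% beta)
  expect_equal(composed_loglik(beta, v, d),
               sum(stats::dnorm(e, 0, sqrt(0.01), log = TRUE)))
})

test_that("the likelihood is invariant to permuting unit blocks", {
  panel <- toy_panel(n_units = 3, T_i = 3)
  df <- as.data.frame(panel)
  perm <- hospital_panel(df[order(df$year, rev(df$hospital_id)), ])
  d1 <- build_design(panel, frontier_spec("cobb_douglas"))
  d2 <- build_design(perm, frontier_spec("cobb_douglas"))
  beta <- toy_beta(d1)
  v <- param_transforms(0.02, 0.004, 0.03)
  expect_equal(composed_loglik(beta, v, d1), composed_loglik(beta, v, d2))
})

test_that("likelihood input validation rejects bad arguments", {
  d <- toy_design(T_i = 2)
  v <- param_transforms(0.02, 0.004)
  expect_error(composed_loglik(rep(0, 3), v, d), "length")
  expect_error(composed_loglik(c(Inf, 0, 0, 0, 0), v, d), "non-finite")
  expect_error(composed_loglik(rep(0, 5), list(sigma_v2 = 1), d), "variance_params")
})

test_that("analytic and numerical gradients agree at random points", {
  d <- toy_design(T_i = 4, n_units = 3)
  beta0 <- toy_beta(d)
  set.seed(42)
  for (rep in 1:5) {
    beta <- beta0 + stats::rnorm(length(beta0), 0, 0.05)
    a <- log(stats::runif(1, 0.005, 0.05))
    g <- stats::rnorm(1, 0, 1.5)
    mu <- stats::rnorm(1, 0, 0.1)
    v <- variance_from_working(a, g, mu)
    th <- c(beta, a, g, mu)
    fn <- function(t) {
      composed_loglik(t[1:5], variance_from_working(t[6], t[7], t[8]), d)
    }
    ga <- hospfrontier:::composed_loglik_grad(beta, v, d)
    gn <- pracma::grad(fn, th)
    expect_lt(max(abs(ga - gn) / pmax(1, abs(gn))), 1e-5)
  }
})

test_that("the noise-free limit is recovered exactly by the fitter", {
  cfg <- generator_config(sigma_u = 0, sigma_v = 0, mu = 0, round_outputs = FALSE)
  sim <- simulate_panel(cfg)
  fit <- fit_frontier(build_design(sim$panel, frontier_spec("cobb_douglas")))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$beta - sim$truth$true_beta)), 1e-8)
})

test_that("maximum likelihood recovers generator truth within 3 standard errors", {
  cfg <- generator_config(n_hospitals = 60, combined_years = integer(0), seed = 3)
  sim <- simulate_panel(cfg)
  d <- build_design(sim$panel, frontier_spec("cobb_douglas"))
  fit <- fit_frontier(d)
  expect_true(fit$converged)
  expect_equal(fit$n_obs, 360)

  truth <- c(sim$truth$true_beta,
             sigma2 = cfg$sigma_u^2 + cfg$sigma_v^2,
             gamma = cfg$sigma_u^2 / (cfg$sigma_u^2 + cfg$sigma_v^2),
             mu = cfg$mu)
  est <- c(fit$beta, sigma2 = fit$variance$sigma2, gamma = fit$variance$gamma,
           mu = fit$variance$mu)
  se <- c(fit$se[seq_along(fit$beta)],
          sigma2 = unname(fit$variance_se["sigma2"]),
          gamma = unname(fit$variance_se["gamma"]),
          mu = unname(fit$variance_se["mu"]))
  expect_true(all(abs(est - truth) <= 3 * se))

  # covariance is symmetric with positive diagonal; Wald test is usable
  expect_equal(fit$covariance, t(fit$covariance))
  expect_true(all(diag(fit$covariance) > 0))
  expect_gt(fit$wald_chi2, 0)
  expect_lt(fit$wald_p, 0.05)
})

test_that("translog log-likelihood dominates nested Cobb-Douglas", {
  wide <- list(beds = c(200, 2000), doctors = c(50, 500),
               nurses = c(200, 2000), nonmedical = c(150, 1500))
  sim <- simulate_panel(generator_config(n_hospitals = 30, combined_years = integer(0),
                                         input_ranges = wide, seed = 9))
  f_cd <- fit_frontier(build_design(sim$panel, frontier_spec("cobb_douglas")))
  f_tl <- fit_frontier(build_design(sim$panel, frontier_spec("translog")))
  expect_true(f_cd$converged && f_tl$converged)
  expect_gte(f_tl$loglik, f_cd$loglik - 1e-6)
})

test_that("adding a constant to the response shifts only the intercept", {
  sim <- simulate_panel(generator_config(n_hospitals = 25, combined_years = integer(0),
                                         round_outputs = FALSE, seed = 15))
  d <- build_design(sim$panel, frontier_spec("cobb_douglas"))
  shift <- log(4)
  d2 <- d
  d2$response <- d$response + shift
  f1 <- fit_frontier(d)
  f2 <- fit_frontier(d2)
  expect_true(f1$converged && f2$converged)
  expect_equal(unname(f2$beta["const"] - f1$beta["const"]), shift, tolerance = 1e-4)
  expect_equal(f2$beta[-1], f1$beta[-1], tolerance = 1e-4)
  expect_equal(f2$variance$sigma2, f1$variance$sigma2, tolerance = 1e-4)
})

test_that("fit reports and serialization are well formed", {
  sim <- simulate_panel(generator_config(n_hospitals = 20, combined_years = integer(0), seed = 2))
  fit <- fit_frontier(build_design(sim$panel, frontier_spec("cobb_douglas")))
  tab <- fit_table(fit)
  expect_equal(tab$parameter[1:5], names(fit$beta))
  expect_true(all(c("sigma_u2", "gamma", "ilgt_gamma", "mu") %in% tab$parameter))
  expect_true(all(tab$p >= 0 & tab$p <= 1, na.rm = TRUE))
  js <- jsonlite::fromJSON(fit_report_json(fit))
  expect_equal(js$loglik, fit$loglik)
  expect_equal(js$n_obs, fit$n_obs)
  expect_output(print(fit), "Log likelihood")
})
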