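# minimal fit object with fixed parameters, for scoring tests that do not
# need an actual optimization
fixed_fit <- function(design, beta, variance) {
  structure(
    list(beta = stats::setNames(beta, colnames(design$X)), variance = variance,
         loglik = 0, converged = TRUE, n_obs = length(design$response),
         n_units = length(unique(design$unit)), spec = design$spec),
    class = "frontier_fit")
}

test_that("efficiency scores match the quadrature oracle at fixed parameters", {
  d <- toy_design(T_i = 3, n_units = 3)
  beta <- toy_beta(d)
  e <- d$response - drop(d$X %*% beta)
  f <- factor(d$unit, levels = unique(d$unit))
  for (pars in list(c(0.02, 0.005, 0.05), c(0.002, 0.01, -0.05), c(0.08, 0.004, 0))) {
    fit <- fixed_fit(d, beta, param_transforms(pars[1], pars[2], pars[3]))
    tab <- bc_efficiency(fit, d)
    scores <- attr(tab, "unit_scores")
    oracle <- vapply(split(e, f), quad_te_unit, numeric(1),
                     sigma_u2 = pars[1], sigma_v2 = pars[2], mu = pars[3])
    expect_equal(unname(scores), unname(oracle), tolerance = 1e-6)
    expect_true(all(scores > 0 & scores <= 1))
  }
})

test_that("scores are replicated across a unit's years and equal for equal residuals", {
  # two units with identical records get identical residual vectors
  df <- as.data.frame(toy_panel(n_units = 1, T_i = 3))
  clone <- df
  clone$hospital_id <- "H2"
  d <- build_design(hospital_panel(rbind(df, clone)), frontier_spec("cobb_douglas"))
  fit <- fixed_fit(d, toy_beta(d), param_transforms(0.02, 0.004, 0.01))
  tab <- bc_efficiency(fit, d)
  scores <- attr(tab, "unit_scores")
  expect_equal(unname(scores["H1"]), unname(scores["H2"]))
  expect_equal(nrow(tab), 6)
  expect_equal(tab$score, unname(scores[tab$unit]))
})

test_that("no inefficiency variance means full efficiency", {
  d <- toy_design(T_i = 2)
  fit <- fixed_fit(d, toy_beta(d), param_transforms(0, 0.004, 0))
  expect_true(all(bc_efficiency(fit, d)$score == 1))
  # and a vanishing (not exactly zero) inefficiency variance approaches 1
  fit2 <- fixed_fit(d, toy_beta(d), param_transforms(1e-12, 0.004, 0))
  expect_true(all(bc_efficiency(fit2, d)$score > 1 - 1e-4))
})

test_that("a larger residual sum gives a weakly larger score", {
  d <- toy_design(T_i = 3, n_units = 4)
  beta <- toy_beta(d)
  fit <- fixed_fit(d, beta, param_transforms(0.03, 0.01, 0.02))
  tab <- bc_efficiency(fit, d)
  e <- d$response - drop(d$X %*% beta)
  sums <- tapply(e, factor(d$unit, levels = unique(d$unit)), sum)
  ord <- order(sums)
  scores <- attr(tab, "unit_scores")[names(sums)]
  expect_true(all(diff(scores[ord]) >= -1e-12))
})

test_that("scoring refuses a non-converged fit or mismatched design", {
  d <- toy_design(T_i = 2)
  fit <- fixed_fit(d, toy_beta(d), param_transforms(0.02, 0.004, 0))
  bad <- fit
  bad$converged <- FALSE
  expect_error(bc_efficiency(bad, d), "converge")
  d2 <- build_design(toy_panel(), frontier_spec("translog"))
  expect_error(bc_efficiency(fit, d2), "match")
})

test_that("summaries have t-intervals, window weighting and error handling", {
  d <- toy_design(T_i = 4, n_units = 3)
  fit <- fixed_fit(d, toy_beta(d), param_transforms(0.02, 0.01, 0))
  tab <- bc_efficiency(fit, d)

  s_all <- summarize_efficiency(tab)
  expect_true(s_all$ci_lower <= s_all$mean && s_all$mean <= s_all$ci_upper)
  expect_equal(s_all$mean, mean(tab$score))

  # record-count-weighted split over sub-windows reproduces the full mean
  s1 <- summarize_efficiency(tab, c(2001, 2002))
  s2 <- summarize_efficiency(tab, c(2003, 2004))
  expect_equal((s1$mean * s1$n + s2$mean * s2$n) / (s1$n + s2$n), s_all$mean)

  expect_error(summarize_efficiency(tab, c(1990, 1995)), "empty")

  # constant scores give a degenerate interval at the value
  const <- tab
  const$score <- 0.9
  s_const <- summarize_efficiency(const)
  expect_equal(s_const$sd, 0)
  expect_equal(c(s_const$ci_lower, s_const$ci_upper), c(0.9, 0.9))
})

test_that("mean estimated efficiency tracks mean true efficiency in simulation", {
  cfg <- generator_config(n_hospitals = 150, combined_years = integer(0), seed = 8)
  sim <- simulate_panel(cfg)
  d <- build_design(sim$panel, frontier_spec("cobb_douglas"))
  fit <- fit_frontier(d)
  tab <- bc_efficiency(fit, d)
  scores <- attr(tab, "unit_scores")
  expect_equal(mean(scores), mean(sim$truth$true_te), tolerance = 0.02)
})

test_that("efficiency tables export to CSV with the spec label", {
  d <- toy_design(T_i = 2)
  fit <- fixed_fit(d, toy_beta(d), param_transforms(0.02, 0.004, 0))
  path <- tempfile(fileext = ".csv")
  write_efficiency(bc_efficiency(fit, d), path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("unit", "year", "score", "spec"))
  expect_true(all(back$spec == "cobb_douglas"))
})
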