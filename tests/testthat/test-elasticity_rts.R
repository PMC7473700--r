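cd_fit <- function(slopes = c(0.232, 0.618, 0.165, 0.228)) {
  structure(
    list(beta = c(const = 5.274, ln_bed = slopes[1], ln_doctor = slopes[2],
                  ln_nurse = slopes[3], ln_nonmedical = slopes[4]),
         spec = frontier_spec("cobb_douglas"), converged = TRUE),
    class = "frontier_fit")
}

tl_fit <- function(beta) {
  structure(list(beta = beta, spec = frontier_spec("translog"), converged = TRUE),
            class = "frontier_fit")
}

tl_beta_names <- function() {
  colnames(build_design(toy_panel(), frontier_spec("translog"))$X)
}

test_that("Cobb-Douglas elasticities are the slopes, at any point", {
  fit <- cd_fit()
  tab <- input_elasticities(fit)
  expect_equal(tab$elasticity, c(0.232, 0.618, 0.165, 0.228))
  tab2 <- input_elasticities(fit, point = c(ln_bed = 9, ln_doctor = 2,
                                            ln_nurse = -1, ln_nonmedical = 0))
  expect_equal(tab2$elasticity, tab$elasticity)
})

test_that("a translog with zero second-order terms reduces to first-order slopes", {
  nm <- tl_beta_names()
  beta <- stats::setNames(rep(0, length(nm)), nm)
  beta[c("const", "ln_bed", "ln_doctor", "ln_nurse", "ln_nonmedical")] <-
    c(1, 0.5, -0.2, 0.7, 0.15)
  tab <- input_elasticities(tl_fit(beta),
                            point = c(ln_bed = 8, ln_doctor = 7, ln_nurse = 8,
                                      ln_nonmedical = 8))
  expect_equal(tab$elasticity, c(0.5, -0.2, 0.7, 0.15))
})

test_that("translog elasticities match a finite-difference oracle", {
  nm <- tl_beta_names()
  set.seed(21)
  beta <- stats::setNames(stats::rnorm(length(nm), 0, 0.3), nm)
  point <- c(ln_bed = 8.1, ln_doctor = 6.9, ln_nurse = 8.2, ln_nonmedical = 8.0)
  fit <- tl_fit(beta)
  tab <- input_elasticities(fit, point = point)

  # independent oracle: central differences of the fitted ln-output surface,
  # built directly from the translog formula
  predict_ln_y <- function(lx) {
    inputs <- c("bed", "doctor", "nurse", "nonmedical")
    y <- beta[["const"]]
    for (v in inputs) y <- y + beta[[paste0("ln_", v)]] * lx[[paste0("ln_", v)]]
    for (i in 1:3) for (j in (i + 1):4) {
      nm_ij <- paste0("ln_", inputs[i], ":ln_", inputs[j])
      y <- y + beta[[nm_ij]] * lx[[paste0("ln_", inputs[i])]] * lx[[paste0("ln_", inputs[j])]]
    }
    for (v in inputs) {
      y <- y + beta[[paste0("half_ln_", v, "_sq")]] * 0.5 * lx[[paste0("ln_", v)]]^2
    }
    y
  }
  h <- 1e-5
  for (i in seq_along(point)) {
    up <- point; up[i] <- up[i] + h
    dn <- point; dn[i] <- dn[i] - h
    fd <- (predict_ln_y(as.list(up)) - predict_ln_y(as.list(dn))) / (2 * h)
    expect_equal(tab$elasticity[i], fd, tolerance = 1e-6)
  }
})

test_that("default evaluation point is the sample mean of logs", {
  sim <- simulate_panel(generator_config(n_hospitals = 10, combined_years = integer(0), seed = 4))
  d <- build_design(sim$panel, frontier_spec("translog"))
  nm <- colnames(d$X)
  set.seed(5)
  beta <- stats::setNames(stats::rnorm(length(nm), 0, 0.2), nm)
  fit <- tl_fit(beta)
  tab_default <- input_elasticities(fit, design = d)
  pt <- colMeans(d$X[, c("ln_bed", "ln_doctor", "ln_nurse", "ln_nonmedical")])
  expect_equal(tab_default$elasticity, input_elasticities(fit, point = pt)$elasticity)
  expect_error(input_elasticities(fit), "point")
  expect_error(input_elasticities(fit, point = pt[-1]), "missing")
})

test_that("scale elasticity sums, exclusions and RTS classes", {
  tab <- elasticity_table(c(beds = 0.51, doctors = -0.24, nurses = 0.73,
                            nonmedical = 0.16))
  rts <- scale_elasticity(tab)
  expect_equal(rts$scale_elasticity, 1.16)
  expect_equal(rts$rts_class, "increasing")

  no_doc <- scale_elasticity(tab, exclude = "doctors")
  expect_equal(no_doc$scale_elasticity, 1.40)
  expect_equal(no_doc$rts_class, "increasing")

  expect_equal(scale_elasticity(elasticity_table(c(a = 0.6, b = 0.4)))$rts_class,
               "constant")
  expect_equal(scale_elasticity(elasticity_table(c(a = 0.5, b = 0.3)))$rts_class,
               "decreasing")
  expect_error(scale_elasticity(tab, exclude = tab$input), "all inputs")
})

test_that("multi-output elasticities include the output-ratio interaction", {
  nm <- colnames(build_design(toy_panel(), frontier_spec("multi_output"))$X)
  beta <- stats::setNames(rep(0, length(nm)), nm)
  beta["ln_bed"] <- 0.4
  beta["ln_bed:ln_ystar"] <- 0.1
  fit <- structure(list(beta = beta, spec = frontier_spec("multi_output"),
                        converged = TRUE), class = "frontier_fit")
  pt <- c(ln_bed = 8, ln_doctor = 7, ln_nurse = 8, ln_nonmedical = 8, ln_ystar = 2)
  tab <- input_elasticities(fit, point = pt)
  expect_equal(tab$elasticity[tab$input == "beds"], 0.4 + 0.1 * 2)
})
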