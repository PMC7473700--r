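# Independent numerical oracles for the composed-error model, used to
# validate the closed-form likelihood and efficiency scores.  All integrate
# the truncated-normal inefficiency u out of a unit's residual density by
# adaptive quadrature over u in [0, Inf).

# marginal log-density of one unit's residual vector
quad_loglik_unit <- function(e_unit, sigma_u2, sigma_v2, mu) {
  su <- sqrt(sigma_u2); sv <- sqrt(sigma_v2)
  f <- function(u) {
    vapply(u, function(ui) {
      exp(sum(stats::dnorm(e_unit + ui, 0, sv, log = TRUE)) +
            stats::dnorm(ui, mu, su, log = TRUE) -
            stats::pnorm(mu / su, log.p = TRUE))
    }, numeric(1))
  }
  log(stats::integrate(f, 0, Inf, rel.tol = 1e-12, abs.tol = 0)$value)
}

# E[exp(-u) | e] under the posterior of u given the unit's residuals
quad_te_unit <- function(e_unit, sigma_u2, sigma_v2, mu) {
  su <- sqrt(sigma_u2); sv <- sqrt(sigma_v2)
  dens <- function(u) {
    vapply(u, function(ui) {
      exp(sum(stats::dnorm(e_unit + ui, 0, sv, log = TRUE)) +
            stats::dnorm(ui, mu, su, log = TRUE))
    }, numeric(1))
  }
  num <- stats::integrate(function(u) exp(-u) * dens(u), 0, Inf,
                          rel.tol = 1e-12, abs.tol = 0)$value
  den <- stats::integrate(dens, 0, Inf, rel.tol = 1e-12, abs.tol = 0)$value
  num / den
}

# small deterministic hospital panel
toy_panel <- function(n_units = 2, T_i = 2, base = 100) {
  rows <- expand.grid(year = 2000 + seq_len(T_i), hospital_id = paste0("H", seq_len(n_units)),
                      stringsAsFactors = FALSE)
  n <- nrow(rows)
  hospital_panel(data.frame(
    hospital_id = rows$hospital_id, year = rows$year,
    beds = base + 7 * seq_len(n), doctors = base + 3 * seq_len(n),
    nurses = base + 11 * seq_len(n), nonmedical = base + 5 * seq_len(n),
    inpatients = 1000 + 13 * seq_len(n), outpatients = 9000 + 17 * seq_len(n)))
}

# Cobb-Douglas design with every unit observed T_i times; residual spread
# controlled by the beta used in the likelihood call, not here
toy_design <- function(T_i, n_units = 3, base = 120) {
  build_design(toy_panel(n_units = n_units, T_i = T_i, base = base),
               frontier_spec("cobb_douglas"))
}

# beta chosen so toy-panel residuals are O(0.1), the scale of the variance
# grids used in the oracle tests; collinear columns of tiny toy designs get
# a zero coefficient
toy_beta <- function(design) {
  b <- stats::lm.fit(design$X, design$response)$coefficients
  b[is.na(b)] <- 0
  b
}
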