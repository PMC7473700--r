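#' Synthetic-panel generator configuration
#'
#' Describes a hospital-year panel drawn from a known production frontier
#' with composed error: inputs log-uniform within per-input ranges, one
#' truncated-normal inefficiency draw `u_i >= 0` per unit (time-invariant),
#' i.i.d. Gaussian noise `v_it`, and
#' `ln(total output) = frontier(ln inputs; true_beta) + v_it - u_i`.
#' Total output is split into outpatient visits and inpatient admissions by
#' `outpatient_share` (deterministically by default, with optional Gaussian
#' jitter on the share so the split itself can be made stochastic).
#'
#' The layout emulates an unbalanced study design: `n_hospitals`
#' disaggregated units observed over `disaggregated_years`, plus one
#' combined pseudo-unit (`combined_unit`) carrying system-wide totals over
#' `combined_years`, treated as one more unit with its own observation
#' window and its own inefficiency draw.
#'
#' @param n_hospitals number of disaggregated hospital units.
#' @param disaggregated_years calendar years for the disaggregated units.
#' @param combined_years calendar years for the combined pseudo-unit
#'   (`NULL` or empty for none).
#' @param combined_unit label of the combined pseudo-unit.
#' @param form frontier functional form generating the data
#'   (`"cobb_douglas"` or `"translog"`; the multi-output distance form is
#'   not a generating model because its regressors involve the outputs).
#' @param true_beta named coefficient vector matching the design columns of
#'   `form` (see [build_design()] naming).
#' @param sigma_u,sigma_v,mu inefficiency scale (`>= 0`), noise scale
#'   (`> 0`) and truncated-normal location.
#' @param input_ranges named list of `c(min, max)` level ranges for
#'   `beds`, `doctors`, `nurses`, `nonmedical` (log-uniform draws).
#' @param outpatient_share share of total output that is outpatient visits,
#'   in `(0, 1)`.
#' @param share_sd standard deviation of an optional per-record Gaussian
#'   jitter on `outpatient_share` (0 = deterministic split).
#' @param round_outputs round the two output counts to integers (`>= 1`), as
#'   real annual statistics are; set `FALSE` for exact-frontier checks in
#'   the deterministic `sigma_u = sigma_v = 0` limit, where rounding would
#'   perturb records off the frontier.
#' @param seed integer RNG seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_hospitals = 5,
                             disaggregated_years = 2001:2006,
                             combined_years = 2007:2017,
                             combined_unit = "ALL",
                             form = "cobb_douglas",
                             true_beta = c(const = 5.0, ln_bed = 0.232,
                                           ln_doctor = 0.618, ln_nurse = 0.165,
                                           ln_nonmedical = 0.228),
                             sigma_u = sqrt(0.018),
                             sigma_v = sqrt(0.004),
                             mu = 0.045,
                             input_ranges = list(beds = c(2603, 3699),
                                                 doctors = c(808, 1514),
                                                 nurses = c(3051, 4016),
                                                 nonmedical = c(2560, 3699)),
                             outpatient_share = 0.886,
                             share_sd = 0,
                             round_outputs = TRUE,
                             seed = 1) {
  form <- match.arg(form, c("cobb_douglas", "translog"))
  stopifnot(n_hospitals >= 1, sigma_u >= 0, sigma_v >= 0,
            outpatient_share > 0, outpatient_share < 1, share_sd >= 0)
  for (v in names(input_ranges)) {
    r <- input_ranges[[v]]
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
      stop("invalid input range for '", v, "'", call. = FALSE)
    }
  }
  if (length(combined_years) > 0 &&
      length(intersect(disaggregated_years, combined_years)) > 0) {
    stop("disaggregated and combined year windows must be disjoint", call. = FALSE)
  }
  structure(
    list(n_hospitals = n_hospitals,
         disaggregated_years = disaggregated_years,
         combined_years = combined_years,
         combined_unit = combined_unit, form = form, true_beta = true_beta,
         sigma_u = sigma_u, sigma_v = sigma_v, mu = mu,
         input_ranges = input_ranges, outpatient_share = outpatient_share,
         share_sd = share_sd, round_outputs = round_outputs, seed = seed,
         notes = if (length(combined_years) > 0)
           "combined pseudo-unit shares the input scale of the range config (scale mix with disaggregated units is not modelled)"
         else NULL),
    class = "generator_config"
  )
}

#' Packaged study-emulation configuration
#'
#' The default generator calibration: 5 regional hospitals observed
#' 2001-2006 plus one combined unit 2007-2017 (41 records), input ranges at
#' the published descriptive-statistics envelopes of the national hospital
#' system (combined scale), Cobb-Douglas frontier with elasticities of
#' plausible magnitude for hospital production, inefficiency share of
#' composed-error variance around 0.8, and an outpatient share of 0.886.
#' A pure function: two calls return identical configurations.
#'
#' @return a [generator_config()].
#' @export
study_emulation_config <- function() generator_config()

# inverse-CDF draw from N(mu, sd^2) truncated to [0, Inf)
rtruncnorm_pos <- function(n, mu, sd) {
  if (sd == 0) return(rep(max(mu, 0), n))
  lo <- stats::pnorm(0, mean = mu, sd = sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean = mu, sd = sd)
}

# frontier regressor matrix from a matrix of log inputs (one column per
# input), matching build_design column naming
frontier_terms <- function(logs, form) {
  inputs <- colnames(logs)
  n <- nrow(logs)
  cols <- list(const = rep(1, n))
  for (v in inputs) cols[[ln_name(v)]] <- logs[, v]
  if (form == "translog") {
    pairs <- utils::combn(inputs, 2, simplify = FALSE)
    for (p in pairs) {
      cols[[paste0(ln_name(p[1]), ":", ln_name(p[2]))]] <- logs[, p[1]] * logs[, p[2]]
    }
    for (v in inputs) cols[[paste0("half_", ln_name(v), "_sq")]] <- 0.5 * logs[, v]^2
  }
  out <- do.call(cbind, cols)
  colnames(out) <- names(cols)
  out
}

#' Simulate a hospital panel with known ground truth
#'
#' Draws a panel under the composed-error frontier model described in
#' [generator_config()].  Identical configurations (including seed) produce
#' bit-identical panels; the caller's RNG state is left untouched.
#'
#' @param config a [generator_config()].
#' @return list with elements:
#'   \describe{
#'     \item{panel}{a [hospital_panel()].}
#'     \item{truth}{list with `true_beta`, `u` (named per-unit inefficiency
#'       draws), `true_te` (`exp(-u)` per unit), `v` (per-record noise), and
#'       `config`.}
#'   }
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  units <- c(if (config$n_hospitals > 0) paste0("H", seq_len(config$n_hospitals)),
             if (length(config$combined_years) > 0) config$combined_unit)
  unit_years <- c(rep(list(config$disaggregated_years), config$n_hospitals),
                  if (length(config$combined_years) > 0) list(config$combined_years))
  n_rec <- sum(lengths(unit_years))

  rec_unit <- rep(seq_along(units), lengths(unit_years))
  rec_year <- unlist(unit_years)

  with_local_seed(config$seed, {
    u <- stats::setNames(rtruncnorm_pos(length(units), config$mu, config$sigma_u),
                         units)
    levels <- vapply(names(config$input_ranges), function(nm) {
      rg <- config$input_ranges[[nm]]
      pmax(1, round(exp(stats::runif(n_rec, log(rg[1]), log(rg[2])))))
    }, numeric(n_rec))
    if (n_rec == 1) levels <- matrix(levels, nrow = 1,
                                     dimnames = list(NULL, names(config$input_ranges)))
    logs <- log(levels)
    terms <- frontier_terms(logs, config$form)
    if (!setequal(colnames(terms), names(config$true_beta))) {
      stop("true_beta names do not match the '", config$form,
           "' design columns", call. = FALSE)
    }
    v_all <- stats::rnorm(n_rec, 0, config$sigma_v)
    ln_y <- drop(terms %*% config$true_beta[colnames(terms)]) + v_all - u[rec_unit]
    total <- exp(ln_y)
    share <- rep(config$outpatient_share, n_rec)
    if (config$share_sd > 0) {
      share <- pmin(pmax(share + stats::rnorm(n_rec, 0, config$share_sd), 1e-6),
                    1 - 1e-6)
    }
    outp <- share * total
    inp <- (1 - share) * total
    if (isTRUE(config$round_outputs)) {
      outp <- round(outp)
      inp <- round(inp)
      if (any(outp < 1) || any(inp < 1)) {
        stop("generator ranges produced a non-positive output count after rounding",
             call. = FALSE)
      }
    }
    panel <- hospital_panel(data.frame(
      hospital_id = units[rec_unit], year = rec_year,
      beds = levels[, "beds"], doctors = levels[, "doctors"],
      nurses = levels[, "nurses"], nonmedical = levels[, "nonmedical"],
      inpatients = inp, outpatients = outp, stringsAsFactors = FALSE))
    list(panel = panel,
         truth = list(true_beta = config$true_beta, u = u,
                      true_te = exp(-u), v = v_all, config = config))
  })
}

#' Analytic mean efficiency of the generator's inefficiency law
#'
#' Closed-form `E[exp(-u)]` for `u ~ N(mu, sigma_u^2)` truncated at zero:
#' `exp(-mu + sigma_u^2/2) * Phi(mu/sigma_u - sigma_u) / Phi(mu/sigma_u)`.
#'
#' @param mu,sigma_u truncated-normal location and scale.
#' @return expected technical efficiency.
#' @export
expected_te <- function(mu, sigma_u) {
  if (sigma_u == 0) return(exp(-max(mu, 0)))
  exp(-mu + sigma_u^2 / 2) *
    stats::pnorm(mu / sigma_u - sigma_u) / stats::pnorm(mu / sigma_u)
}

#' Write a simulated panel and its ground truth to disk
#'
#' The panel goes to CSV (see [write_panel()]) and the ground truth to a
#' JSON side-file with the same stem.
#'
#' @param sim a [simulate_panel()] result.
#' @param path panel CSV path; the truth file replaces the extension with
#'   `_truth.json`.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  write_panel(sim$panel, path)
  truth_path <- paste0(sub("\\.csv$", "", path), "_truth.json")
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  truth$u <- as.list(truth$u)
  truth$true_te <- as.list(truth$true_te)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
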