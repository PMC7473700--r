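---
title: "Methods: panel stochastic frontiers for hospital efficiency and fiscal space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel stochastic frontiers for hospital efficiency and fiscal space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hospfrontier)
```

This vignette is the package's own account of its statistical machinery:
the model and its assumptions, the numerical choices that make the
likelihood reliable, what the synthetic-data generator does and does not
emulate, and the design decisions taken where more than one reasonable
implementation existed.

## The composed-error panel frontier

The observed log output of hospital $i$ in year $t$ is modelled as

$$\ln y_{it} = \mathbf{x}_{it}'\boldsymbol\beta + v_{it} - u_i,$$

with $v_{it} \sim N(0, \sigma_v^2)$ i.i.d. noise and $u_i \ge 0$ a
*time-invariant* inefficiency drawn once per hospital from
$N(\mu, \sigma_u^2)$ truncated at zero.  Time invariance is a real
restriction: one draw of $u_i$ governs all of a hospital's years, and the
Battese–Coelli efficiency score for that hospital is constant over its
observation window (the package broadcasts it to unit-years purely for
reporting).  Panels may be unbalanced — each unit brings its own $T_i$ —
and a combined pseudo-unit (label `"ALL"`) carrying system-wide totals for
years without disaggregated records is treated as one more unit with its
own window and its own $u_i$.  That a single likelihood then mixes
per-hospital-scale and system-scale observations is a property of the
emulated study design, not something the package attempts to repair; the
generator flags it in its `notes` field.

The marginal likelihood integrates $u_i$ out per unit.  With per-unit
residual statistics $S_1 = \sum_t e_{it}$, $S_2 = \sum_t e_{it}^2$ and
$D = \sigma_v^2 + T_i \sigma_u^2$, the closed form involves the posterior
location $\mu_i^* = (\mu\sigma_v^2 - \sigma_u^2 S_1)/D$ and scale
$\sigma_*^2 = \sigma_u^2\sigma_v^2/D$.  `composed_loglik()` evaluates it in
log space and is tested against adaptive quadrature of the defining
integral to $10^{-6}$ per unit across a grid of $\gamma$, $\mu$ and $T_i$.

### Parameterization and a numerical pitfall

Reporting uses the conventional $\sigma^2 = \sigma_u^2 + \sigma_v^2$ and
variance ratio $\gamma = \sigma_u^2/\sigma^2$, with unconstrained
transforms $\ln\sigma^2$ and $\mathrm{logit}(\gamma)$.  The optimizer,
however, does **not** use $\mu$ itself as its fourth coordinate.  Written
naively, the closed form subtracts $\mu^2/2\sigma_u^2$ from a posterior
term of the same magnitude; as $\gamma \to 0$ both grow without bound and
floating-point cancellation noise creates spurious likelihood spikes that a
quasi-Newton optimizer will happily climb.  The package therefore evaluates
the combined term algebraically (so the $\gamma \to 0$ limit is *exactly*
the pooled Gaussian log-likelihood) and optimizes the scaled location
$m = \mu/\sigma_u$, which is also the statistically natural coordinate:
as $\gamma \to 0$, $\mu$ is unidentified while $m$ remains well behaved.
Standard errors for $\mu$ and the derived variance quantities come from the
delta method on the observed information (numerical Hessian at the
optimum).

### Optimization protocol

* Starting values are corrected-OLS style: OLS slopes, $\sigma^2$ at the
  OLS residual variance, $\gamma = 0.5$, $m = 0$.
* BFGS with the analytic gradient (validated against numerical
  differentiation to $10^{-5}$), `reltol` $10^{-12}$, up to 2000
  iterations.
* Five starts by default: the corrected-OLS start plus four jittered
  copies (fixed jitter seed in `frontier_control()`).  Composed-error
  likelihoods are genuinely multi-modal — on 41-record panels a mode with
  $\gamma$ near zero (pooled regression) frequently coexists with the
  interior mode, and single-start estimation can land on either.
* Non-convergence is reported (`converged = FALSE` with the optimizer
  trace), never silently patched; efficiency scoring refuses such fits.
* Rank-deficient designs (e.g. the output-ratio block when the outpatient
  share barely varies) get zero starting values for the collinear columns
  and a recorded warning; a Wald statistic that comes out negative because
  the information matrix is not positive definite is reported as `NA`
  rather than as a number.

## Functional forms and their term sets

`build_design()` expands a panel into the regressor matrix with a
deterministic column order (constant, first-order logs, pairwise
interactions in lexicographic order, half-squares, then the output-ratio
block).  The $\tfrac12$ factor on own second-order terms lives in the
design column, so reported coefficients follow the
$\beta_{jj}\,0.5(\ln x_j)^2$ convention.  Slope counts are 4
(Cobb–Douglas), 14 (translog) and 20 (multi-output distance).

The multi-output distance form regresses $\ln(\text{outpatients})$ on the
translog set plus $\ln Y^*$, its interactions with each input, and
$0.5(\ln Y^*)^2$, where $Y^*$ is the outpatient/inpatient ratio.  This is
implemented literally as specified, including its awkward feature that the
response appears inside $Y^*$; the package neither instruments nor
normalizes it away, and treats the form as a reporting variant rather than
a structurally identified model.

## Efficiency scores

`bc_efficiency()` returns $TE_i = E[\exp(-u_i)\mid e_{i1},\dots,e_{iT_i}]$
in closed form, checked against quadrature to $10^{-6}$ including $\gamma$
near 0 and near 0.95.  Scores exceeding 1 by less than $10^{-12}$ (pure
floating-point) are clipped to 1; anything larger is treated as an internal
error, not clipped.  Summaries are means over unit-year scores with a
t-interval; the paired comparison between two specifications
(`paired_t()`) pairs unit-year scores.

## Elasticities and returns to scale

For the translog form the elasticity of input $j$ at log-input point
$\mathbf{z}$ is $\beta_j + \sum_{h\neq j}\beta_{jh} z_h + \beta_{jj} z_j$;
the multi-output form adds $\beta_{jY^*}\ln Y^*$.  The default evaluation
point is the sample mean of the log inputs (the geometric mean of levels)
— the convention that makes translog first-order coefficients directly
interpretable; every report states the point used.  The scale elasticity is
the sum over included inputs, classified as increasing/constant/decreasing
returns against 1 with tolerance $10^{-9}$ on exact sums.  A published
variant of the elasticity formula carries a time-trend-like term although
no model here includes a time trend; the package implements the standard
translog derivative, which is also what a finite-difference check of the
fitted surface reproduces.

## Fiscal space

`savings()` is the linear gap formula
$(\mathrm{eff}_{target}-\mathrm{eff}_{baseline})\times G$.  Report cells
are rounded half-up (commercial rounding) to the nearest MUR million —
R's default banker's rounding would disagree with printed budget tables on
half-million cells — while unrounded values are retained.  Shares of
general government health expenditure are only computed when GGHE levels
are supplied by the user; the package ships no GGHE series.

## The synthetic-data generator

`simulate_panel()` draws input levels log-uniformly within per-input
ranges (guaranteeing positivity without truncation artifacts), one
truncated-normal $u_i$ per unit, i.i.d. noise, and splits total output into
outpatients/inpatients by a fixed share.  The packaged calibration
`study_emulation_config()` emulates the study design the package is built
around:

* layout 5 disaggregated hospitals × 2001–2006 plus one combined unit ×
  2007–2017 (41 records);
* input ranges at the published descriptive-statistics envelopes of the
  combined hospital system (beds 2603–3699, doctors 808–1514, nurses
  3051–4016, non-medical 2560–3699).  The published table is internally
  inconsistent in places (the beds and non-medical rows print identical
  mean/sd), so these ranges are treated as approximate calibration, not as
  a distributional target;
* Cobb–Douglas truth with slopes (0.232, 0.618, 0.165, 0.228) — published
  point estimates of plausible magnitude for hospital production — and
  intercept 5.0, chosen once so simulated output magnitudes land at the
  published output scale (≈1.2–1.9 million annual contacts);
* $\sigma_u^2 = 0.018$, $\sigma_v^2 = 0.004$ ($\gamma \approx 0.82$),
  $\mu = 0.045$, implying mean true efficiency
  $E[\exp(-u)] \approx 0.886$, matching the published mean-efficiency
  range (0.83–0.89);
* outpatient share 0.886, the published outpatient/total ratio.

The split is deterministic by default; `share_sd` adds Gaussian jitter
when the multi-output form is to be fitted on synthetic data, because a
perfectly constant split makes the $Y^*$ block collinear.  Outputs are
rounded to integer counts by default; `round_outputs = FALSE` exists for
exact-frontier checks in the deterministic $\sigma_u = \sigma_v = 0$
limit, where rounding would perturb records off the frontier.

What the generator does **not** emulate: case-mix and severity, quality of
care, length-of-stay dynamics, serial correlation in inputs, time-varying
efficiency, or the unknown joint distribution of the real system's inputs.
Passing tests on synthetic panels therefore demonstrate correctness of the
estimation machinery under the model's own assumptions, not that the model
describes any particular hospital system.

## Validation experiments and their problem sizes

The test suite fixes these sizes as the package's standard evidence:

* **Oracle grids** — likelihood and efficiency scores vs quadrature on
  $\gamma \in \{0.05, 0.5, 0.95\}$, $\mu \in \{-0.1, 0, 0.1\}$,
  $T_i \in \{1, 3, 6\}$, tolerance $10^{-6}$.
* **Parameter recovery** — 20 replicate panels of 200 units × 6 years at
  the study-emulation calibration; every true parameter within 3 reported
  standard errors in at least 18 of 20 runs, and Spearman correlation
  between estimated and true efficiency above 0.9.
* **Null calibration of the LR test** — 500 replicate panels drawn from a
  Cobb–Douglas truth, translog vs Cobb–Douglas LR at level 0.05 expected
  to reject 5% ± 2.5%.  These panels use 60 units × 6 years with wider
  input ranges (e.g. beds 200–2000): the study-emulation ranges are so
  narrow on the log scale that the ten second-order translog terms are
  nearly collinear and the $\chi^2_{10}$ asymptotics need substantially
  larger samples.  60 × 6 is the smallest size at which a pilot showed the
  asymptotic size holding; two optimizer starts per fit keep the
  experiment's cost proportionate.

## Known limitations

* The time-invariant model cannot express efficiency trends; year-resolved
  trajectories require windowed refits, which the pipeline exposes but
  does not dress up as a time-varying estimator.
* The multi-output distance form is estimated as printed, with the output
  ratio on both sides; its coefficients should be read descriptively.
* On 41-record panels the translog and multi-output fits are heavily
  parameterized (up to 24 free parameters); standard errors there lean on
  asymptotics that thin data cannot fully support, and the information
  matrix may not be positive definite — the fit object says so rather than
  hiding it.
* The boundary-parameter mixed chi-square issue for testing $\gamma$
  itself is documented but not implemented; the LR test here concerns only
  the second-order $\beta$ terms, which are interior.
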