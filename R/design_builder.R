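#' Frontier functional-form specification
#'
#' Three production-frontier forms over the four hospital inputs
#' (beds, doctors, nurses, non-medical staff):
#'
#' * `"cobb_douglas"`: log-linear, response `ln(outpatients + inpatients)`,
#'   4 slope parameters.
#' * `"translog"`: adds all pairwise interactions `ln x_j * ln x_h` (j < h)
#'   and own second-order terms `0.5 * (ln x_j)^2`, 14 slope parameters.
#' * `"multi_output"`: an output distance form; the response is
#'   `ln(outpatients)` and the translog regressor set is augmented with
#'   `ln Y*`, its interactions with each input, and `0.5 * (ln Y*)^2`, where
#'   `Y*` is the ratio of outpatient visits to inpatient admissions;
#'   20 slope parameters.
#'
#' The 1/2 factor on own second-order terms lives in the design column, so
#' reported coefficients follow the `b_jj * 0.5 * (ln x_j)^2` convention.
#'
#' @param form one of `"cobb_douglas"`, `"translog"`, `"multi_output"`.
#' @return An object of class `frontier_spec` with fields `form`, `inputs`
#'   and `output_mode` (`"aggregate"` or `"distance"`).
#' @export
frontier_spec <- function(form = c("cobb_douglas", "translog", "multi_output")) {
  form <- match.arg(form)
  structure(
    list(form = form,
         inputs = c("beds", "doctors", "nurses", "nonmedical"),
         output_mode = if (form == "multi_output") "distance" else "aggregate"),
    class = "frontier_spec"
  )
}

#' @export
print.frontier_spec <- function(x, ...) {
  cat("Frontier specification: ", x$form, " (", x$output_mode, " output), ",
      n_slopes(x), " slope parameter(s)\n", sep = "")
  invisible(x)
}

#' Number of slope parameters of a frontier form
#'
#' Excludes the intercept: 4 for Cobb-Douglas, 14 for translog, 20 for the
#' multi-output distance form.
#'
#' @param spec a [frontier_spec()].
#' @return integer count.
#' @export
n_slopes <- function(spec) {
  k <- length(spec$inputs)
  as.integer(switch(spec$form,
                    cobb_douglas = k,
                    translog = k + choose(k, 2) + k,
                    multi_output = k + choose(k, 2) + k + 1 + k + 1))
}

ln_name <- function(v) paste0("ln_", sub("s$", "", v))

#' Expand a panel into a frontier design matrix
#'
#' Builds the response vector and regressor matrix for a functional form.
#' Column order is deterministic: constant, first-order log inputs in input
#' order, pairwise interactions in lexicographic pair order, half-squares in
#' input order, then (multi-output only) the `ln Y*` block.
#'
#' @param panel a [hospital_panel()].
#' @param spec a [frontier_spec()].
#' @return An object of class `frontier_design` with fields:
#'   \describe{
#'     \item{response}{numeric vector of log outputs.}
#'     \item{X}{numeric matrix, named columns, constant first.}
#'     \item{unit}{character vector of hospital ids per row.}
#'     \item{year}{integer vector of calendar years per row.}
#'     \item{term_catalog}{data frame mapping each column to its kind
#'       (constant / first_order / interaction / half_square / ystar /
#'       ystar_interaction / half_ystar_square) and parent variables.}
#'     \item{spec}{the `frontier_spec`.}
#'   }
#' @export
build_design <- function(panel, spec) {
  stopifnot(inherits(panel, "hospital_panel"), inherits(spec, "frontier_spec"))
  inputs <- spec$inputs
  for (v in inputs) {
    if (any(panel[[v]] <= 0)) stop("design domain error: non-positive '", v, "'", call. = FALSE)
  }
  if (any(panel$outpatients <= 0) || any(panel$inpatients <= 0)) {
    stop("design domain error: non-positive output", call. = FALSE)
  }

  logs <- lapply(inputs, function(v) log(panel[[v]]))
  names(logs) <- inputs
  n <- nrow(panel)

  cols <- list(const = rep(1, n))
  catalog <- data.frame(column = "const", kind = "constant", parents = "",
                        stringsAsFactors = FALSE)
  add <- function(name, values, kind, parents) {
    cols[[name]] <<- values
    catalog <<- rbind(catalog, data.frame(column = name, kind = kind,
                                          parents = paste(parents, collapse = ":"),
                                          stringsAsFactors = FALSE))
  }

  for (v in inputs) add(ln_name(v), logs[[v]], "first_order", v)

  if (spec$form %in% c("translog", "multi_output")) {
    pairs <- utils::combn(inputs, 2, simplify = FALSE)
    for (p in pairs) {
      add(paste0(ln_name(p[1]), ":", ln_name(p[2])),
          logs[[p[1]]] * logs[[p[2]]], "interaction", p)
    }
    for (v in inputs) {
      add(paste0("half_", ln_name(v), "_sq"), 0.5 * logs[[v]]^2, "half_square", v)
    }
  }

  if (spec$form == "multi_output") {
    ln_ystar <- log(panel$outpatients) - log(panel$inpatients)
    add("ln_ystar", ln_ystar, "ystar", "ystar")
    for (v in inputs) {
      add(paste0(ln_name(v), ":ln_ystar"), logs[[v]] * ln_ystar,
          "ystar_interaction", c(v, "ystar"))
    }
    add("half_ln_ystar_sq", 0.5 * ln_ystar^2, "half_ystar_square", "ystar")
  }

  response <- if (spec$output_mode == "aggregate") {
    log(panel$outpatients + panel$inpatients)
  } else {
    log(panel$outpatients)
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(
    list(response = response, X = X, unit = panel$hospital_id,
         year = as.integer(panel$year), term_catalog = catalog, spec = spec),
    class = "frontier_design"
  )
}

#' @export
print.frontier_design <- function(x, ...) {
  cat("Frontier design (", x$spec$form, "): ", length(x$response), " rows, ",
      ncol(x$X), " columns (", ncol(x$X) - 1L, " slopes), ",
      length(unique(x$unit)), " unit(s)\n", sep = "")
  invisible(x)
}

#' Export a design matrix for audit
#'
#' Writes response, unit, year and all regressor columns as CSV with the
#' deterministic column names.
#'
#' @param design a [build_design()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  df <- data.frame(unit = design$unit, year = design$year,
                   response = design$response, design$X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
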