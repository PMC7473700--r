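#' Output elasticities of the inputs at an evaluation point
#'
#' The elasticity of output with respect to input `j` is the derivative of
#' fitted log output in the log input, evaluated at a point:
#' * Cobb-Douglas: `e_j = b_j` (point-free);
#' * translog: `e_j = b_j + sum_{h != j} b_jh ln x_h + b_jj ln x_j`
#'   (the half-square design convention makes the own term enter once);
#' * multi-output distance: additionally `+ b_{j,Y*} ln Y*` from the
#'   output-ratio interaction.
#'
#' The default evaluation point is the per-input mean of the log levels over
#' the estimation sample (the geometric mean of the levels), which is the
#' convention that makes translog first-order coefficients directly
#' interpretable; reports state the point used.
#'
#' @param fit a [fit_frontier()] result.
#' @param point named numeric vector of log levels (`ln_bed`, `ln_doctor`,
#'   `ln_nurse`, `ln_nonmedical`, plus `ln_ystar` for the multi-output form).
#'   `NULL` uses the sample mean of the design's log columns.
#' @param design the design the fit was estimated on; required when `point`
#'   is `NULL`.
#' @return An `elasticity_table` data frame with columns `input`,
#'   `elasticity`, and the evaluation point as attribute `point`.
#' @export
input_elasticities <- function(fit, point = NULL, design = NULL) {
  stopifnot(inherits(fit, "frontier_fit"))
  spec <- fit$spec
  inputs <- spec$inputs
  ln_inputs <- vapply(inputs, ln_name, character(1))

  needed <- ln_inputs
  if (spec$form == "multi_output") needed <- c(needed, "ln_ystar")

  if (is.null(point)) {
    if (spec$form == "cobb_douglas") {
      point <- stats::setNames(rep(NA_real_, length(needed)), needed)
    } else {
      if (is.null(design)) {
        stop("a design (or an explicit point) is required to set the evaluation point",
             call. = FALSE)
      }
      point <- colMeans(design$X[, needed, drop = FALSE])
    }
  }
  missing_pt <- setdiff(needed, names(point))
  if (spec$form != "cobb_douglas" && length(missing_pt) > 0) {
    stop("evaluation point missing: ", paste(missing_pt, collapse = ", "),
         call. = FALSE)
  }

  beta <- fit$beta
  elas <- vapply(seq_along(inputs), function(j) {
    lj <- ln_inputs[j]
    e <- beta[[lj]]
    if (spec$form %in% c("translog", "multi_output")) {
      for (h in seq_along(inputs)) {
        if (h == j) next
        nm <- if (h > j) paste0(lj, ":", ln_inputs[h]) else paste0(ln_inputs[h], ":", lj)
        e <- e + beta[[nm]] * point[[ln_inputs[h]]]
      }
      e <- e + beta[[paste0("half_", lj, "_sq")]] * point[[lj]]
    }
    if (spec$form == "multi_output") {
      e <- e + beta[[paste0(lj, ":ln_ystar")]] * point[["ln_ystar"]]
    }
    e
  }, numeric(1))

  elasticity_table(stats::setNames(elas, inputs), point = point,
                   form = spec$form)
}

#' Construct an elasticity table from per-input values
#'
#' Useful for scale-elasticity arithmetic on externally reported
#' elasticities as well as for [input_elasticities()] output.
#'
#' @param elasticities named numeric vector, one entry per input.
#' @param point optional evaluation point (named log levels).
#' @param form optional functional-form label.
#' @return An `elasticity_table` data frame with columns `input`,
#'   `elasticity`.
#' @export
elasticity_table <- function(elasticities, point = NULL, form = NULL) {
  stopifnot(is.numeric(elasticities), !is.null(names(elasticities)))
  structure(
    data.frame(input = names(elasticities), elasticity = unname(elasticities),
               row.names = NULL),
    point = point, form = form,
    class = c("elasticity_table", "data.frame")
  )
}

#' Scale elasticity and returns-to-scale classification
#'
#' Sums the per-input output elasticities (optionally excluding some inputs,
#' i.e. holding them constant) and classifies returns to scale: increasing
#' if the sum exceeds 1 by more than `tol`, constant if within `tol` of 1,
#' decreasing otherwise.
#'
#' @param table an [elasticity_table()].
#' @param exclude character vector of input names to hold constant.
#' @param tol classification tolerance around 1.
#' @return list with `scale_elasticity`, `rts_class` (one of `"decreasing"`,
#'   `"constant"`, `"increasing"`) and `included` inputs.
#' @export
scale_elasticity <- function(table, exclude = NULL, tol = 1e-9) {
  stopifnot(inherits(table, "elasticity_table"))
  keep <- !(table$input %in% exclude)
  if (!any(keep)) stop("exclusion removes all inputs", call. = FALSE)
  s <- sum(table$elasticity[keep])
  cls <- if (s > 1 + tol) "increasing" else if (abs(s - 1) <= tol) "constant" else "decreasing"
  list(scale_elasticity = s, rts_class = cls, included = table$input[keep])
}

#' Write an elasticity table to CSV with an RTS statement
#'
#' @param table an [elasticity_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_elasticities <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  rts <- scale_elasticity(table)
  cat(sprintf("Total,%.*g\n", 15, rts$scale_elasticity), file = path, append = TRUE)
  invisible(path)
}

#' @export
print.elasticity_table <- function(x, ...) {
  cat("Output elasticities (", attr(x, "form") %||% "unspecified form", ")\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  rts <- scale_elasticity(x)
  cat(sprintf("Scale elasticity %.4g: %s returns to scale\n",
              rts$scale_elasticity, rts$rts_class))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
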