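#' Pipeline run configuration
#'
#' Drives [run_pipeline()] end to end.  Supply either an input panel (a
#' [hospital_panel()] or a CSV path) or a [generator_config()] for a
#' simulated run.
#'
#' @param panel a `hospital_panel`, a CSV path, or `NULL` to simulate.
#' @param generator a [generator_config()] used when `panel` is `NULL`.
#' @param specs functional forms to fit.
#' @param efficiency_windows named list of year ranges for efficiency
#'   summaries; `NULL` summarizes the full period.
#' @param scenario `NULL` or a list with `baselines`, `targets`, `budgets`
#'   (named by fiscal year) and optional `gghe` for the fiscal-space stage.
#' @param control a [frontier_control()] for all fits.
#' @param seed seed for the simulated-input path (overrides the generator's).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(panel = NULL, generator = study_emulation_config(),
                            specs = c("cobb_douglas", "translog", "multi_output"),
                            efficiency_windows = NULL, scenario = NULL,
                            control = frontier_control(), seed = NULL) {
  specs <- match.arg(specs, c("cobb_douglas", "translog", "multi_output"),
                     several.ok = TRUE)
  if (length(specs) == 0) stop("at least one specification is required", call. = FALSE)
  if (!is.null(seed) && !is.null(generator)) generator$seed <- seed
  structure(list(panel = panel, generator = generator, specs = specs,
                 efficiency_windows = efficiency_windows, scenario = scenario,
                 control = control, seed = seed),
            class = "pipeline_config")
}

stage_result <- function(expr, stage) {
  tryCatch(list(ok = TRUE, value = expr, error = NULL),
           error = function(e) list(ok = FALSE, value = NULL,
                                    error = paste0("[", stage, "] ", conditionMessage(e))))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate the panel; descriptive summary; one
#' maximum-likelihood frontier fit per requested specification; the
#' likelihood-ratio test of translog against Cobb-Douglas (when both are
#' fitted); Battese-Coelli efficiency tables and summaries per converged
#' fit; output elasticities at the sample geometric mean (from the translog
#' fit when available, otherwise the first converged fit); the
#' fiscal-space scenario grid.  A failed stage is recorded in `$errors` and
#' downstream-independent stages still run.  Deterministic given the
#' configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @return list of class `analysis_report` with elements `panel`, `summary`,
#'   `fits`, `lr`, `efficiency`, `efficiency_summaries`, `elasticities`,
#'   `scenarios`, `errors`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  errors <- character(0)
  note_err <- function(res) {
    if (!res$ok) errors <<- c(errors, res$error)
    res$value
  }

  panel <- if (is.null(config$panel)) {
    simulate_panel(config$generator)$panel
  } else if (is.character(config$panel)) {
    load_panel(config$panel)
  } else {
    config$panel
  }

  summary_tab <- note_err(stage_result(summarize_panel(panel), "summary"))

  fits <- list(); designs <- list()
  for (form in config$specs) {
    res <- stage_result({
      d <- build_design(panel, frontier_spec(form))
      f <- fit_frontier(d, control = config$control)
      list(design = d, fit = f)
    }, paste0("fit:", form))
    v <- note_err(res)
    if (!is.null(v)) {
      fits[[form]] <- v$fit
      designs[[form]] <- v$design
    }
  }

  lr <- NULL
  if (all(c("cobb_douglas", "translog") %in% names(fits)) &&
      fits$cobb_douglas$converged && fits$translog$converged) {
    lr <- note_err(stage_result(
      lr_test(fits$cobb_douglas$loglik, fits$translog$loglik,
              df = n_slopes(frontier_spec("translog")) -
                n_slopes(frontier_spec("cobb_douglas"))),
      "lr_test"))
  }

  efficiency <- list(); eff_summaries <- list()
  for (form in names(fits)) {
    if (!isTRUE(fits[[form]]$converged)) next
    tab <- note_err(stage_result(bc_efficiency(fits[[form]], designs[[form]]),
                                 paste0("efficiency:", form)))
    if (is.null(tab)) next
    efficiency[[form]] <- tab
    windows <- config$efficiency_windows %||% list(full = range(tab$year))
    eff_summaries[[form]] <- do.call(rbind, lapply(windows, function(w) {
      summarize_efficiency(tab, window = w)
    }))
  }

  elasticities <- NULL
  elas_form <- if ("translog" %in% names(fits)) "translog" else names(fits)[1]
  if (!is.null(elas_form) && length(elas_form) == 1 && !is.na(elas_form) &&
      isTRUE(fits[[elas_form]]$converged)) {
    elasticities <- note_err(stage_result(
      input_elasticities(fits[[elas_form]], design = designs[[elas_form]]),
      "elasticity"))
  }

  scenarios <- NULL
  if (!is.null(config$scenario)) {
    sc <- config$scenario
    scenarios <- note_err(stage_result(
      scenario_grid(sc$baselines, sc$targets, sc$budgets, gghe = sc$gghe),
      "fiscal_space"))
  }

  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(list(specs = config$specs, seed = config$seed,
                            generator = if (is.null(config$panel))
                              unclass(config$generator)),
                       cfg_file, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  provenance <- list(config_md5 = unname(tools::md5sum(cfg_file)),
                     seed = config$seed,
                     package_version = as.character(utils::packageVersion("hospfrontier")))
  unlink(cfg_file)

  structure(
    list(panel = panel, summary = summary_tab, fits = fits, lr = lr,
         efficiency = efficiency, efficiency_summaries = eff_summaries,
         elasticities = elasticities, scenarios = scenarios, errors = errors,
         provenance = provenance),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report\n===============\n")
  cat("Panel:", nrow(x$panel), "records,",
      length(attr(x$panel, "units")), "units\n\n")
  for (form in names(x$fits)) {
    print(x$fits[[form]])
    cat("\n")
  }
  if (!is.null(x$lr)) {
    cat("Translog vs Cobb-Douglas: ")
    print(x$lr)
  }
  for (form in names(x$efficiency_summaries)) {
    cat("\nEfficiency summary (", form, "):\n", sep = "")
    print(x$efficiency_summaries[[form]], row.names = FALSE)
  }
  if (!is.null(x$elasticities)) {
    cat("\n")
    print(x$elasticities)
  }
  if (!is.null(x$scenarios)) {
    cat("\nFiscal-space scenarios:\n")
    print(as.data.frame(x$scenarios), row.names = FALSE)
  }
  if (length(x$errors) > 0) {
    cat("\nStage errors:\n", paste(" -", x$errors, collapse = "\n"), "\n")
  }
  invisible(x)
}
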