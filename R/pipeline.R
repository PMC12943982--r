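#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis so a run is fully
#' reproducible from its config and seed; the config is echoed verbatim
#' into the run report.
#'
#' @param input path to a phenotype CSV, or NULL to generate synthetic data
#'   from `synth`.
#' @param synth a `synth_config` used when `input` is NULL.
#' @param alpha significance level for term selection (default 0.05).
#' @param max_fdr false-discovery rate for the outlier screen
#'   (default 0.30).
#' @param rel_tol singular-value truncation (default 1e-10).
#' @param tss total-sum-of-squares convention (see
#'   [performance_measures()]).
#' @param n_mc Monte-Carlo pseudo-realities for the normality test
#'   (default 10000).
#' @param ci_level interval coverage for downstream prediction
#'   (default 0.50).
#' @param seed integer seed for the diagnostic Monte-Carlo.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, synth = synth_config(),
                       alpha = 0.05, max_fdr = 0.30, rel_tol = 1e-10,
                       tss = "auto", n_mc = 10000L, ci_level = 0.5,
                       seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, max_fdr > 0, max_fdr < 1,
            rel_tol > 0, n_mc >= 100, ci_level > 0, ci_level < 1)
  structure(
    list(input = input, synth = synth, alpha = alpha, max_fdr = max_fdr,
         rel_tol = rel_tol, tss = tss, n_mc = as.integer(n_mc),
         ci_level = ci_level, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full modelling pipeline
#'
#' Executes, in order: data load (or synthetic generation); full quadratic
#' design; three-phase stepwise term selection; cyclic outlier screening on
#' the selected structure; refit on the purged records; HC3 covariance and
#' holdout performance measures; model-adequacy ANOVA, error-nullity test,
#' heteroskedasticity test and Monte-Carlo normality test. Every stage's
#' output lands in the returned report.
#'
#' @param config a `run_config`.
#' @param data optionally, a phenotype data frame overriding
#'   `config$input` / `config$synth`.
#' @return A `run_report` list: config echo, selection trace and counts,
#'   outlier cycle reports, the final `mlr_fit` and `final_model`,
#'   performance measures under both TSS conventions, and all diagnostic
#'   p-values and verdicts.
#' @export
cmd_fit <- function(config = run_config(), data = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- "input"
  report <- list(config = config,
                 version = as.character(utils::packageVersion("saltreg")))
  tryCatch({
    if (is.null(data)) {
      data <- if (!is.null(config$input)) {
        read_phenotypes(config$input)
      } else {
        generate_phenotypes(config$synth)$data
      }
    } else {
      data <- as_phenotypes(data)
    }
    report$n_input <- nrow(data)

    stage <- "selection"
    sel <- run_msra(data, alpha = config$alpha, rel_tol = config$rel_tol)
    report$selected_terms <- sel$terms$label
    report$msra_trace <- sel$trace
    report$msra_phase_counts <- sel$phase_counts
    if (nrow(sel$terms) == 0L) {
      stop("no term is ever significant at alpha = ", config$alpha)
    }

    stage <- "outlier_screen"
    cod <- run_codpa(data, sel$terms, max_fdr = config$max_fdr,
                     rel_tol = config$rel_tol)
    report$codpa_cycles <- cod$cycles
    report$codpa_flags_per_cycle <-
      vapply(cod$cycles, function(cy) length(cy$record_ids), integer(1))
    report$removed_ids <- cod$removed_ids
    report$n_retained <- nrow(cod$data)

    stage <- "refit"
    fit <- fit_svd(build_design(cod$data, sel$terms),
                   rel_tol = config$rel_tol)
    report$fit <- fit
    report$slopes <- fit$slopes
    report$hc3_sd <- sqrt(diag(fit$hc3_cov))
    report$hc3_cov <- fit$hc3_cov
    report$resid_sd <- fit$resid_sd
    report$dof <- fit$dof

    stage <- "measures"
    report$measures <- performance_measures(fit, tss = config$tss)
    report$measures_uncentered <- performance_measures(fit, "uncentered")
    report$measures_centered <- performance_measures(fit, "centered")

    stage <- "diagnostics"
    report$adequacy_p <- adequacy_anova(fit, tss = config$tss)
    report$nullity_p <- error_nullity_test(fit)
    report$mhtra <- run_mhtra(cod$data, fit, rel_tol = config$rel_tol)
    report$mc_jb <- mc_jarque_bera(fit$resid, n_mc = config$n_mc,
                                   seed = config$seed)

    report$model <- as_final_model(fit, provenance = "pipeline refit")
    report$status <- "ok"
    class(report) <- "run_report"
    report
  }, error = function(e) {
    report$status <- "failed"
    report$failed_stage <- stage
    report$error <- conditionMessage(e)
    class(report) <- "run_report"
    report
  })
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (saltreg", x$version, ") status:", x$status, "\n")
  if (x$status != "ok") {
    cat("failed at stage:", x$failed_stage, "-", x$error, "\n")
    return(invisible(x))
  }
  cat("records:", x$n_input, "input,", x$n_retained, "retained (",
      length(x$removed_ids), "outliers over",
      length(x$codpa_cycles), "cycles:",
      paste(x$codpa_flags_per_cycle, collapse = ","), ")\n")
  cat("selection steps per phase:",
      paste(x$msra_phase_counts, collapse = "/"),
      "-> terms:", paste(x$selected_terms, collapse = ", "), "\n")
  print(x$fit)
  print(x$measures)
  cat(sprintf("adequacy ANOVA p = %.3g; nullity p = %.3g\n",
              x$adequacy_p, x$nullity_p))
  cat(sprintf("heteroskedasticity: aux F p = %.4g, aux R2_adj = %.3g (%s)\n",
              x$mhtra$anova_p, x$mhtra$aux_r2_adj, x$mhtra$verdict))
  cat(sprintf("Monte-Carlo Jarque-Bera: JB = %.3g, p = %.4g (%d draws)\n",
              x$mc_jb$jb_stat, x$mc_jb$p_value, x$mc_jb$n_mc))
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' @param report a `run_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  obj <- report
  obj$fit <- NULL
  obj$model <- NULL
  obj$config$synth <- unclass(obj$config$synth)
  obj$config <- unclass(obj$config)
  if (!is.null(obj$measures)) obj$measures <- unclass(obj$measures)
  if (!is.null(obj$measures_uncentered)) {
    obj$measures_uncentered <- unclass(obj$measures_uncentered)
  }
  if (!is.null(obj$measures_centered)) {
    obj$measures_centered <- unclass(obj$measures_centered)
  }
  obj <- unclass(obj)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  invisible(path)
}

#' Write scenario prediction tables
#'
#' Thin prediction front-end: loads a model (a JSON file written by
#' [write_model_json()], a `final_model`, or NULL for the bundled
#' reference model), evaluates a figure template or custom scenario, and
#' optionally writes the table as CSV.
#'
#' @param model a `final_model`, a path to a model JSON, or NULL for
#'   [rice_sdw_model()].
#' @param figure figure template number (1-5), ignored when `spec` given.
#' @param spec optional custom `scenario_spec`.
#' @param level interval coverage (default 0.50).
#' @param out optional CSV output path.
#' @return The scenario table (invisibly if written to `out`).
#' @export
cmd_predict <- function(model = NULL, figure = 1, spec = NULL,
                        level = 0.5, out = NULL) {
  if (is.null(model)) {
    model <- rice_sdw_model()
  } else if (is.character(model)) {
    model <- read_model_json(model)
  }
  stopifnot(inherits(model, "final_model"))
  if (is.null(spec)) spec <- figure_scenario(figure, level = level)
  tab <- scenario_grid(model, spec)
  if (!is.null(out)) {
    utils::write.csv(tab, out, row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Generate and write a synthetic phenotype table
#'
#' Wrapper over [generate_phenotypes()] that writes the table in the
#' canonical CSV dialect and the ground truth (true slopes, outlier ids,
#' seed) as a JSON side-car.
#'
#' @param config a `synth_config`.
#' @param out CSV output path.
#' @param truth_out optional JSON path for the ground truth.
#' @return The generated data frame, invisibly.
#' @export
cmd_simulate <- function(config = synth_config(), out,
                         truth_out = NULL) {
  gen <- generate_phenotypes(config)
  write_phenotypes(gen$data, out)
  if (!is.null(truth_out)) {
    jsonlite::write_json(
      list(seed = config$seed,
           true_slopes = as.list(gen$truth$true_slopes),
           outlier_ids = gen$truth$outlier_ids,
           noise_sd = config$noise_sd),
      truth_out, auto_unbox = TRUE, digits = NA)
  }
  invisible(gen$data)
}
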