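resolve_dataset <- function(dataset) {
  if (inherits(dataset, "protein_dataset")) return(dataset)
  if (is.character(dataset) && length(dataset) == 1) {
    if (dataset == "acid") return(load_acid_dataset())
    if (dataset == "alkali") return(load_alkali_dataset())
    return(read_protein_dataset(dataset))
  }
  stop("resolve_dataset: expected a protein_dataset, 'acid', 'alkali', ",
       "or a file path", call. = FALSE)
}

fit_report_list <- function(fit) {
  list(
    catalyst = fit$catalyst,
    solution_form = fit$model_config$solution_form,
    energy_scale = fit$model_config$energy_scale,
    params = as.list(unclass(fit$params)),
    sse = fit$sse,
    r_squared = fit$r_squared,
    residuals = fit$residuals,
    seed = fit$seed,
    n_starts = fit$n_starts,
    best_start_index = fit$best_start_index,
    converged = fit$converged,
    n_function_evals = fit$n_function_evals
  )
}

#' Fit workflow: fit a dataset and write report files
#'
#' Runs [fit_kinetics()] and writes three files under `output_dir`:
#' `fit_report.json` (machine-readable, full precision),
#' `fit_report.txt` (key-value, 4 significant figures) and
#' `residuals.csv` (per-observation measured, predicted, residual). Output
#' is byte-reproducible for a fixed seed and configuration.
#'
#' @param dataset a `protein_dataset`, the fixture name `"acid"` or
#'   `"alkali"`, or a file path.
#' @param output_dir directory for the report files (created if absent).
#' @param config a [fit_config()].
#' @param model_config a [model_config()].
#' @param range_filter drop rows outside the applicable ranges before
#'   fitting (default `FALSE`: reproduce the full-table fit).
#' @return The `kinetic_fit`, invisibly; report paths in attribute
#'   `"paths"`.
#' @export
run_fit_workflow <- function(dataset, output_dir,
                             config = fit_config(),
                             model_config = sludgekin::model_config(),
                             range_filter = FALSE) {
  ds <- resolve_dataset(dataset)
  violations <- validate_ranges(ds, warn = FALSE)
  if (range_filter) ds <- filter_ranges(ds)
  fit <- fit_kinetics(ds, config, model_config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  rep <- fit_report_list(fit)
  rep$n_observations <- nrow(ds$data)
  rep$range_filtered <- range_filter
  rep$range_violations <- violations
  json_path <- file.path(output_dir, "fit_report.json")
  jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  txt_path <- file.path(output_dir, "fit_report.txt")
  p <- unclass(fit$params)
  lines <- c(
    sprintf("catalyst: %s", fit$catalyst),
    sprintf("solution_form: %s", fit$model_config$solution_form),
    sprintf("energy_scale: %g", fit$model_config$energy_scale),
    sprintf("n_observations: %d", nrow(ds$data)),
    sprintf("range_filtered: %s", range_filter),
    sprintf("%s: %.4g", names(p), p),
    sprintf("sse: %.4g", fit$sse),
    sprintf("r_squared: %.4g", fit$r_squared),
    sprintf("seed: %d", fit$seed),
    sprintf("n_starts: %d", fit$n_starts))
  writeLines(lines, txt_path)

  res_path <- file.path(output_dir, "residuals.csv")
  res <- cbind(as.data.frame(dataset_conditions(ds)),
               measured = ds$data$protein_mg_L,
               predicted = fit$fitted,
               residual = fit$residuals)
  write.csv(res, res_path, row.names = FALSE, quote = FALSE)

  attr(fit, "paths") <- c(json = json_path, txt = txt_path, residuals = res_path)
  invisible(fit)
}

#' Prediction workflow: evaluate the model on a condition grid
#'
#' @param params a [kinetic_params()] vector or the path of a
#'   `fit_report.json` written by [run_fit_workflow()].
#' @param conditions a [reaction_conditions()] data frame.
#' @param path optional CSV output path; the table is written in the
#'   standard dataset format with the protein column named `predicted`.
#' @param config a [model_config()].
#' @return Data frame of conditions plus `predicted` (mg/L).
#' @export
run_predict_workflow <- function(params, conditions, path = NULL,
                                 config = model_config()) {
  if (is.character(params) && length(params) == 1) {
    rep <- jsonlite::read_json(params, simplifyVector = TRUE)
    params <- do.call(kinetic_params, rep$params)
  }
  out <- cbind(as.data.frame(conditions),
               predicted = protein_timecourse(conditions, params, config))
  if (!is.null(path)) write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}

#' Simulation workflow: generate and write a synthetic dataset
#'
#' @param design a [synthetic_design()] or [reference_design()].
#' @param params true [kinetic_params()].
#' @param path output CSV path; a `#` provenance line records the seed,
#'   noise model and true parameters.
#' @param config a [model_config()].
#' @return The generated `protein_dataset`, invisibly.
#' @export
run_simulate_workflow <- function(design, params, path,
                                  config = model_config()) {
  ds <- generate_dataset(design, params, config)
  prov <- sprintf(
    "synthetic: seed=%d noise=%s scale=%g true=[%s]",
    design$seed, design$noise_model, design$noise_scale,
    paste(sprintf("%s=%g", names(unclass(params)), unclass(params)),
          collapse = " "))
  write_protein_dataset(ds, path, provenance = prov)
  invisible(ds)
}

#' Recovery workflow: run a recovery experiment and write its report
#'
#' @param params_true true [kinetic_params()].
#' @param design a [synthetic_design()].
#' @param output_dir directory for `recovery_report.json`.
#' @param fit_cfg a [fit_config()].
#' @param model_cfg a [model_config()].
#' @return The `recovery_report`, invisibly.
#' @export
run_recover_workflow <- function(params_true, design, output_dir,
                                 fit_cfg = fit_config(),
                                 model_cfg = model_config()) {
  rec <- recovery_experiment(params_true, design, fit_cfg, model_cfg)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(
    true_params = as.list(unclass(rec$true_params)),
    fitted_params = as.list(unclass(rec$fitted_params)),
    param_rel_error = as.list(rec$param_rel_error),
    derived_rel_error = as.list(rec$derived_rel_error),
    curve_discrepancy = rec$curve_discrepancy,
    noise_model = rec$noise_model,
    noise_scale = rec$noise_scale,
    clamped_fraction = rec$clamped_fraction,
    n_observations = rec$n_observations,
    seed = rec$seed)
  jsonlite::write_json(out, file.path(output_dir, "recovery_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rec)
}
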