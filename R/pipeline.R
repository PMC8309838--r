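#' Run the full two-stage evolutionary pipeline
#'
#' Composes the stages end to end: optional feature extraction from ROI
#' pairs, model selection (bucket of models), then feature selection scored
#' by the selected models. Both stages share one run-level seed, hence one
#' stratified 70/30 holdout split; the final model and mask are scored once
#' on the holdout part.
#'
#' @param data a feature table (tibble with `class` column), or a list of
#'   labeled [roi_pair()]s together with `group`.
#' @param group feature group name, required when `data` is a list of exams.
#' @param ms_config a [ga_config()] for the model-selection stage.
#' @param fs_config an [fs_config()] for the feature-selection stage.
#' @param space a [build_parameter_space()].
#' @param seed run-level seed; overrides the seeds in both stage configs so
#'   the whole run is reproducible from one integer.
#' @param verbose print per-generation progress.
#' @return A `thermoga_pipeline` object: `model_selection`,
#'   `feature_selection`, `metrics` (five holdout metrics as percentages,
#'   2 decimals), `selected_features`, `final_model`, `audit` (per-stage and
#'   total trained-model counts), `seed`.
#' @examples
#' \donttest{
#' tab <- synth_feature_table(n_exams = 40, n_features = 10, seed = 3)$table
#' tiny <- run_pipeline(tab,
#'   ms_config = ga_config(population_size = 4, generations = 2,
#'     quotas = c(selection = 1, crossover = 2, asexual = 0, mutation = 0,
#'                random = 1)),
#'   fs_config = fs_config(population_size = 4, generations = 2,
#'     quotas = c(selection = 1, crossover = 2, mutation = 0, random = 1)),
#'   seed = 3)
#' tiny$audit$total_trained  # 16
#' }
#' @export
run_pipeline <- function(data,
                         group = NULL,
                         ms_config = ga_config(),
                         fs_config = thermoga::fs_config(),
                         space = build_parameter_space(),
                         seed = 1,
                         verbose = FALSE) {
  if (!is.data.frame(data)) {
    if (is.null(group)) abort("extraction stage: 'group' is required for ROI input")
    data <- extract_table(data, group)
  }
  ms_config$seed <- as.integer(seed)
  fs_config$seed <- as.integer(seed)

  ms <- tryCatch(
    run_model_selection(data, ms_config, space, verbose = verbose),
    error = function(e) abort(paste0("model-selection stage: ", conditionMessage(e)))
  )
  fs <- tryCatch(
    run_feature_selection(data, ms, fs_config, protocol = ms$protocol,
                          verbose = verbose),
    error = function(e) abort(paste0("feature-selection stage: ", conditionMessage(e)))
  )

  metrics <- dplyr::mutate(fs$holdout,
                           dplyr::across(dplyr::everything(),
                                         ~ round(100 * .x, 2)))
  structure(list(
    model_selection = ms,
    feature_selection = fs,
    metrics = metrics,
    selected_features = names(which(fs$best_mask)),
    final_model = fs$best_model,
    audit = list(
      model_selection_trained = ms$audit$trained_models,
      feature_selection_trained = fs$audit$trained_models,
      total_trained = ms$audit$trained_models + fs$audit$trained_models,
      decimations = c(model_selection = ms$audit$decimations,
                      feature_selection = fs$audit$decimations)
    ),
    seed = as.integer(seed)
  ), class = "thermoga_pipeline")
}

#' @export
print.thermoga_pipeline <- function(x, ...) {
  cat("Two-stage evolutionary pipeline\n")
  cat(sprintf("  models trained: %d (selection) + %d (features) = %d\n",
              x$audit$model_selection_trained, x$audit$feature_selection_trained,
              x$audit$total_trained))
  cat(sprintf("  final model: %s\n", x$final_model$key))
  cat(sprintf("  selected features: %d of %d\n",
              length(x$selected_features),
              length(x$feature_selection$best_mask)))
  cat(sprintf("  holdout (%%): AUC %.2f  F1 %.2f  ACC %.2f  SENS %.2f  SPEC %.2f\n",
              x$metrics$auc, x$metrics$f1, x$metrics$acc,
              x$metrics$sens, x$metrics$spec))
  invisible(x)
}

#' Training budget relative to the exhaustive grid
#'
#' Summarizes how many models the evolutionary search trains against the size
#' of the exhaustive hyperparameter grid. The percentage of the
#' model-selection stage is truncated to two decimals and the total
#' percentage is rounded to two decimals, matching the reporting convention
#' of the study design this package follows.
#'
#' @param ms_trained models trained during model selection.
#' @param total_trained models trained by both stages.
#' @param space a [build_parameter_space()].
#' @return A one-row tibble: `exhaustive`, `ms_trained`, `total_trained`,
#'   `ms_pct`, `total_pct`.
#' @examples
#' training_budget(4200, 18200)
#' @export
training_budget <- function(ms_trained, total_trained,
                            space = build_parameter_space()) {
  exhaustive <- count_exhaustive(space)
  tibble::tibble(
    exhaustive = exhaustive,
    ms_trained = ms_trained,
    total_trained = total_trained,
    ms_pct = floor(ms_trained / exhaustive * 100 * 100) / 100,
    total_pct = round(total_trained / exhaustive * 100, 2)
  )
}

#' Write a pipeline report as JSON
#'
#' Serializes the final report: metrics (percent, 2 decimals), selected
#' columns, the final model's canonical form and concrete parameters, audit
#' counters, protocol and seed.
#'
#' @param pipeline a `thermoga_pipeline`.
#' @param path destination file; `NULL` returns the JSON string.
#' @return The path (or the JSON string), invisibly.
#' @export
report_json <- function(pipeline, path = NULL) {
  stopifnot(inherits(pipeline, "thermoga_pipeline"))
  fs <- pipeline$feature_selection
  rep <- list(
    metrics_pct = as.list(pipeline$metrics),
    selected_features = pipeline$selected_features,
    final_model = list(
      canonical = pipeline$final_model$key,
      parameters = pipeline$final_model$config[param_names()],
      fitness = pipeline$final_model$fitness
    ),
    audit = pipeline$audit,
    protocol = list(
      holdout_fraction = fs$protocol$holdout_fraction,
      cv_folds = fs$protocol$cv_folds,
      seed = fs$protocol$seed
    ),
    seed = pipeline$seed
  )
  json <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}
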