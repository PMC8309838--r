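#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the bucket of models
#'
#' One row per returned model: rank, fitness, kernel and the concrete values
#' of the kernel-relevant hyperparameters.
#'
#' @param x a `ga_model_selection` object.
#' @param ... unused.
#' @return A tibble.
#' @method tidy ga_model_selection
#' @export
tidy.ga_model_selection <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$top_models), function(i) {
    m <- x$top_models[[i]]
    rel <- x$space$relevance[[m$config$kernel]]
    row <- tibble::tibble(rank = i, fitness = m$fitness,
                          kernel = m$config$kernel,
                          canonical = m$key)
    for (p in setdiff(param_names(), "kernel")) {
      row[[p]] <- if (p %in% rel) m$config[[p]] else NA_real_
    }
    row
  }))
}

#' @rdname tidy.ga_model_selection
#' @method glance ga_model_selection
#' @export
glance.ga_model_selection <- function(x, ...) {
  tibble::tibble(
    best_fitness = x$top_models[[1]]$fitness,
    trained_models = x$audit$trained_models,
    generations = x$audit$generations,
    population_size = x$audit$population_size,
    decimations = x$audit$decimations,
    seed = x$cfg$seed
  )
}

#' Tidy a feature-selection run
#'
#' One row per feature column with its selection state in the returned mask.
#'
#' @param x a `ga_feature_selection` object.
#' @param ... unused.
#' @return A tibble with columns `feature` and `selected`.
#' @method tidy ga_feature_selection
#' @export
tidy.ga_feature_selection <- function(x, ...) {
  tibble::tibble(feature = names(x$best_mask),
                 selected = unname(x$best_mask))
}

#' @rdname tidy.ga_feature_selection
#' @method glance ga_feature_selection
#' @export
glance.ga_feature_selection <- function(x, ...) {
  tibble::tibble(
    best_fitness = x$best_score,
    n_active = x$n_active,
    n_features = length(x$best_mask),
    holdout_auc = x$holdout$auc,
    trained_models = x$audit$trained_models,
    generations = x$audit$generations,
    population_size = x$audit$population_size,
    decimations = x$audit$decimations,
    seed = x$cfg$seed
  )
}

#' Tidy a pipeline report
#'
#' The five holdout metrics in long form (percent scale).
#'
#' @param x a `thermoga_pipeline` object.
#' @param ... unused.
#' @return A tibble with columns `metric` and `value_pct`.
#' @method tidy thermoga_pipeline
#' @export
tidy.thermoga_pipeline <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value_pct")
}

#' @rdname tidy.thermoga_pipeline
#' @method glance thermoga_pipeline
#' @export
glance.thermoga_pipeline <- function(x, ...) {
  tibble::tibble(
    holdout_auc_pct = x$metrics$auc,
    n_selected = length(x$selected_features),
    n_features = length(x$feature_selection$best_mask),
    total_trained = x$audit$total_trained,
    seed = x$seed
  )
}
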