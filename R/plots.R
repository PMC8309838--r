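#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   scale_x_continuous theme_minimal
#' @export
ggplot2::autoplot

ga_trace_plot <- function(history, subtitle) {
  df <- tidyr::pivot_longer(
    dplyr::select(history, "generation", "best_fitness", "median_fitness"),
    cols = c("best_fitness", "median_fitness"),
    names_to = "series", values_to = "fitness"
  )
  ggplot(df, aes(x = .data$generation, y = .data$fitness,
                 colour = .data$series)) +
    geom_line() +
    geom_point(data = dplyr::filter(history, .data$decimated),
               aes(x = .data$generation, y = .data$best_fitness),
               inherit.aes = FALSE, shape = 4, size = 2) +
    labs(x = "generation", y = "fitness (mean CV AUC)",
         colour = NULL, title = "Evolution of fitness",
         subtitle = subtitle,
         caption = "crosses mark decimation (perturbation) events") +
    theme_minimal()
}

#' Fitness trace of a model-selection run
#' @param object a `ga_model_selection` object.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot ga_model_selection
#' @export
autoplot.ga_model_selection <- function(object, ...) {
  ga_trace_plot(object$history, "model selection (bucket of models)")
}

#' Fitness trace of a feature-selection run
#' @param object a `ga_feature_selection` object.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot ga_feature_selection
#' @export
autoplot.ga_feature_selection <- function(object, ...) {
  ga_trace_plot(object$history, "feature selection")
}

#' Selected-feature map of a feature-selection run
#'
#' Bar chart of the returned mask: which feature columns the evolutionary
#' search kept.
#'
#' @param x a `ga_feature_selection` object.
#' @return A ggplot.
#' @export
plot_selected_features <- function(x) {
  stopifnot(inherits(x, "ga_feature_selection"))
  df <- tidy(x)
  df$index <- seq_len(nrow(df))
  ggplot(df, aes(x = .data$index, y = as.integer(.data$selected))) +
    ggplot2::geom_col(width = 1) +
    labs(x = "feature column", y = "selected",
         title = sprintf("Selected %d of %d features",
                         sum(df$selected), nrow(df))) +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
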