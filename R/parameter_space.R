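#' SVM hyperparameter search space
#'
#' The discrete grid of nu-SVM hyperparameters explored by the model-selection
#' genetic algorithm: ordered candidate lists for tolerance (8 values, 0.1 down
#' to 1e-8 by decades), gamma and coef0 (58 values each: 1e-8 to 0.1 by decades,
#' then 0.2 to 5.1 in steps of 0.1), nu (0.2-0.6), polynomial degree (1-3) and
#' kernel (rbf, poly, sigmoid), together with a kernel-to-relevant-parameters
#' map. Two configurations that differ only in a parameter the kernel ignores
#' (e.g. coef0 under rbf) denote the same model; the canonical form of a
#' configuration keeps only the kernel-relevant values.
#'
#' @param tolerance,gamma,coef0,nu,degree,kernel optional overrides for the
#'   candidate value lists. Defaults are the full grid described above.
#' @return An object of class `parameter_space`: a list of ordered candidate
#'   vectors plus a `relevance` map.
#' @examples
#' space <- build_parameter_space()
#' lengths(space[param_names()])
#' count_exhaustive(space)
#' @export
build_parameter_space <- function(tolerance = 10^-(1:8),
                                  gamma = c(10^-(8:1), seq(0.2, 5.1, by = 0.1)),
                                  coef0 = gamma,
                                  nu = c(0.2, 0.3, 0.4, 0.5, 0.6),
                                  degree = c(1, 2, 3),
                                  kernel = c("rbf", "poly", "sigmoid")) {
  space <- list(
    tolerance = tolerance, gamma = gamma, coef0 = coef0,
    nu = nu, degree = degree, kernel = kernel,
    relevance = list(
      rbf     = c("tolerance", "gamma", "nu"),
      poly    = c("tolerance", "gamma", "coef0", "degree", "nu"),
      sigmoid = c("tolerance", "gamma", "coef0", "nu")
    )
  )
  for (k in kernel) {
    if (is.null(space$relevance[[k]])) {
      abort(sprintf("no relevance set defined for kernel '%s'", k))
    }
  }
  structure(space, class = "parameter_space")
}

#' Gene order of a model genome
#'
#' Fixed order of the six hyperparameter genes in a model genome.
#' @return Character vector of the six parameter names.
#' @export
param_names <- function() {
  c("tolerance", "gamma", "coef0", "nu", "degree", "kernel")
}

#' Count the exhaustive model grid
#'
#' Number of distinct canonical SVM configurations in a parameter space: the
#' sum over kernels of the product of that kernel's relevant-parameter list
#' lengths. This is the number of models a grid search would have to train,
#' the yardstick against which the genetic algorithm's training budget is
#' measured.
#'
#' @param space a [build_parameter_space()] object.
#' @param per_kernel if `TRUE`, return a tibble with one row per kernel.
#' @return A single integer count, or a tibble with columns `kernel` and
#'   `n_models` when `per_kernel = TRUE`.
#' @examples
#' count_exhaustive(build_parameter_space())  # 540560
#' @export
count_exhaustive <- function(space, per_kernel = FALSE) {
  stopifnot(inherits(space, "parameter_space"))
  counts <- vapply(space$kernel, function(k) {
    rel <- setdiff(space$relevance[[k]], "kernel")
    prod(vapply(rel, function(p) length(space[[p]]), numeric(1)))
  }, numeric(1))
  if (per_kernel) {
    tibble::tibble(kernel = space$kernel, n_models = unname(counts))
  } else {
    sum(counts)
  }
}

#' Decode a model genome into a concrete SVM configuration
#'
#' A model genome is a vector of six 1-based indices, one per hyperparameter in
#' [param_names()] order, into the candidate lists of the parameter space.
#'
#' @param genome integer vector of six indices.
#' @param space a [build_parameter_space()] object.
#' @return A `model_config`: named list with one concrete value per parameter
#'   plus the kernel name.
#' @export
decode_genome <- function(genome, space) {
  genome <- as.integer(genome)
  nm <- param_names()
  if (length(genome) != length(nm)) {
    abort(sprintf("model genome must have %d genes", length(nm)))
  }
  for (i in seq_along(nm)) {
    if (genome[i] < 1L || genome[i] > length(space[[nm[i]]])) {
      abort(sprintf(
        "gene '%s' index %d out of bounds [1, %d]",
        nm[i], genome[i], length(space[[nm[i]]])
      ))
    }
  }
  cfg <- stats::setNames(
    lapply(seq_along(nm), function(i) space[[nm[i]]][genome[i]]), nm
  )
  structure(cfg, class = "model_config")
}

#' Encode a configuration back into genome indices
#' @param config a `model_config`.
#' @param space a [build_parameter_space()] object.
#' @return Integer vector of six indices.
#' @export
encode_genome <- function(config, space) {
  nm <- param_names()
  vapply(nm, function(p) {
    i <- match(config[[p]], space[[p]])
    if (is.na(i)) abort(sprintf("value of '%s' not in parameter space", p))
    as.integer(i)
  }, integer(1))
}

#' Canonical form of a configuration
#'
#' Projects a configuration onto its kernel-relevant parameters and formats
#' them as a stable string key. Two genomes that differ only in parameters the
#' kernel ignores map to the same canonical form.
#'
#' @param config a `model_config`.
#' @param space a [build_parameter_space()] object.
#' @return A single character key, e.g. `"rbf|tolerance=0.001|gamma=0.5|nu=0.4"`.
#' @export
canonical_config <- function(config, space) {
  rel <- space$relevance[[config$kernel]]
  rel <- intersect(param_names(), rel)  # fixed order
  paste(
    c(config$kernel,
      vapply(rel, function(p) {
        paste0(p, "=", format(config[[p]], digits = 15, scientific = FALSE))
      }, character(1))),
    collapse = "|"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat("nu-SVM configuration\n")
  for (p in param_names()) {
    cat(sprintf("  %-9s %s\n", p, format(x[[p]])))
  }
  invisible(x)
}

random_model_genome <- function(space) {
  vapply(param_names(), function(p) sample.int(length(space[[p]]), 1L),
         integer(1))
}

genome_valid <- function(genome, space) {
  nm <- param_names()
  length(genome) == length(nm) &&
    all(genome >= 1L) &&
    all(genome <= vapply(nm, function(p) length(space[[p]]), integer(1)))
}
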