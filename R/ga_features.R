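#' Configuration of the feature-selection genetic algorithm
#'
#' Defaults follow the study design: 140 binary-chromosome individuals evolved
#' for 100 generations with quotas of 20 elites, 40 crossover children, 6
#' mutants and 74 random genomes (asexual plus/minus-one reproduction does not
#' apply to binary genes). Fitness is supplied by the bucket of models from
#' the first stage: in `top_model` mode (default) each individual is scored by
#' the rank-1 model only, so one model is trained per individual; in
#' `model_set_max` mode the individual's score is the maximum over all
#' returned models.
#'
#' @param population_size individuals per generation.
#' @param generations number of generations.
#' @param quotas named vector `selection`, `crossover`, `mutation`, `random`;
#'   must sum to `population_size`.
#' @param min_active minimum number of active genes any individual may have.
#' @param perturbation_patience flat-fitness generations before decimation.
#' @param fitness_mode `"top_model"` or `"model_set_max"`.
#' @param seed run-level seed.
#' @return An `fs_config` list.
#' @export
fs_config <- function(population_size = 140,
                      generations = 100,
                      quotas = c(selection = 20, crossover = 40, mutation = 6,
                                 random = 74),
                      min_active = 1,
                      perturbation_patience = 10,
                      fitness_mode = c("top_model", "model_set_max"),
                      seed = 1) {
  quotas <- quotas[c("selection", "crossover", "mutation", "random")]
  if (anyNA(quotas) || any(quotas < 0)) {
    abort("quotas must name selection, crossover, mutation, random (all >= 0)")
  }
  if (sum(quotas) != population_size) {
    abort(sprintf("quotas sum to %d but population_size is %d",
                  sum(quotas), population_size))
  }
  stopifnot(is_count(population_size), is_count(generations),
            is_count(min_active), is_count(perturbation_patience))
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 quotas = quotas,
                 min_active = as.integer(min_active),
                 perturbation_patience = as.integer(perturbation_patience),
                 fitness_mode = match.arg(fitness_mode),
                 seed = as.integer(seed)),
            class = "fs_config")
}

repair_min_active <- function(bits, min_active) {
  deficit <- min_active - sum(bits)
  if (deficit > 0) {
    off <- which(!bits)
    on <- if (length(off) == 1) off else sample(off, deficit)
    bits[on] <- TRUE
  }
  bits
}

random_feature_genome <- function(d, min_active) {
  repair_min_active(runif(d) < 0.5, min_active)
}

#' Single-point ("cutoff") crossover of binary feature genomes
#'
#' Child 1 takes the first `cutoff` genes of parent 1 and the remainder of
#' parent 2; child 2 takes the complementary assignment. Children falling
#' below `min_active` active genes are repaired by activating random inactive
#' genes.
#'
#' @param p1,p2 logical parent genomes of equal length.
#' @param cutoff cut position, strictly between 0 and the genome length.
#' @param min_active minimum active genes per child.
#' @return List of two children.
#' @export
crossover_bits <- function(p1, p2, cutoff, min_active = 1) {
  d <- length(p1)
  stopifnot(length(p2) == d, cutoff >= 1, cutoff < d)
  d1 <- c(p1[seq_len(cutoff)], p2[seq(cutoff + 1, d)])
  d2 <- c(p2[seq_len(cutoff)], p1[seq(cutoff + 1, d)])
  list(repair_min_active(d1, min_active), repair_min_active(d2, min_active))
}

#' Single-bit mutation of a feature genome
#'
#' Flips exactly one randomly chosen bit. A flip that would drop the genome
#' below `min_active` active genes is not allowed; an activation (or a
#' different bit) is chosen instead.
#'
#' @param bits logical genome.
#' @param min_active minimum active genes.
#' @return Genome at Hamming distance 1 from the input.
#' @export
mutate_bit <- function(bits, min_active = 1) {
  d <- length(bits)
  # activations are always legal; deactivations only above the floor
  legal <- which(!bits | sum(bits) > min_active)
  if (length(legal) == 0) return(bits)
  g <- if (length(legal) == 1) legal else sample(legal, 1)
  bits[g] <- !bits[g]
  bits
}

#' Fitness of a feature subset under the bucket of models
#'
#' Scores a binary genome by the mean inner-CV ROC AUC of the selected
#' model(s) restricted to the active columns. Ties between genomes are broken
#' in favour of fewer active genes, honouring the goal of the smallest subset
#' that best describes the problem.
#'
#' @param bits logical genome over the feature columns.
#' @param models list of model entries (as in `ga_model_selection$top_models`).
#' @param ds dataset from [dataset_matrix()].
#' @param protocol an [make_eval_protocol()].
#' @param fitness_mode `"top_model"` or `"model_set_max"`.
#' @return List with `score`, `n_active`, `model_index` (which model produced
#'   the score) and `trained` (models trained for this evaluation).
#' @export
feature_fitness <- function(bits, models, ds, protocol,
                            fitness_mode = "top_model") {
  if (!any(bits)) {
    return(list(score = 0, n_active = 0L, model_index = NA_integer_, trained = 0L))
  }
  if (fitness_mode == "top_model") {
    res <- evaluate_config(models[[1]]$config, ds, protocol, mask = bits)
    list(score = res$fitness, n_active = sum(bits), model_index = 1L, trained = 1L)
  } else {
    scores <- vapply(models, function(m) {
      evaluate_config(m$config, ds, protocol, mask = bits)$fitness
    }, numeric(1))
    best <- which.max(scores)
    list(score = scores[best], n_active = sum(bits), model_index = best,
         trained = length(models))
  }
}

next_generation_features <- function(ranked_pop, cfg) {
  q <- cfg$quotas
  n <- nrow(ranked_pop)
  d <- ncol(ranked_pop)
  elite_n <- min(q[["selection"]], n)
  elites <- ranked_pop[seq_len(elite_n), , drop = FALSE]
  parts <- list(selection = elites)
  strat <- rep("selection", nrow(elites))

  n_children <- q[["crossover"]]
  kids <- matrix(NA, n_children, d)
  i <- 1L
  while (i <= n_children) {
    couple <- if (nrow(elites) > 1) sample.int(nrow(elites), 2) else c(1L, 1L)
    cutoff <- if (d == 2) 1L else sample(seq_len(d - 1L), 1)
    ch <- crossover_bits(elites[couple[1], ], elites[couple[2], ],
                         cutoff, cfg$min_active)
    kids[i, ] <- ch[[1]]
    if (i + 1L <= n_children) kids[i + 1L, ] <- ch[[2]]
    i <- i + 2L
  }
  parts$crossover <- kids
  strat <- c(strat, rep("crossover", n_children))

  n_mut <- q[["mutation"]]
  if (n_mut > 0) {
    picks <- integer(n_mut)
    picks[1] <- sample.int(min(3L, n), 1)
    if (n_mut >= 2) picks[2] <- n - sample.int(min(3L, n), 1) + 1L
    if (n_mut >= 3) picks[3:n_mut] <- sample.int(n, n_mut - 2L, replace = TRUE)
    muts <- t(vapply(picks, function(p) mutate_bit(ranked_pop[p, ], cfg$min_active),
                     logical(d)))
    parts$mutation <- muts
    strat <- c(strat, rep("mutation", n_mut))
  }

  if (q[["random"]] > 0) {
    rnd <- t(vapply(seq_len(q[["random"]]),
                    function(i) random_feature_genome(d, cfg$min_active),
                    logical(d)))
    parts$random <- rnd
    strat <- c(strat, rep("random", q[["random"]]))
  }

  pop <- do.call(rbind, parts)
  rownames(pop) <- NULL
  list(pop = pop, strategy = strat)
}

#' Evolve feature subsets scored by the bucket of models
#'
#' Runs the binary-chromosome genetic algorithm over the feature columns of a
#' table, using the models returned by [run_model_selection()] as the fitness
#' function. Individuals are ranked by score (mean inner-CV AUC), ties broken
#' by fewer active genes, then by earlier discovery. Returns the best mask
#' ever seen together with the model that scored it and its holdout metrics.
#'
#' @param data feature table (see [dataset_matrix()]).
#' @param models a `ga_model_selection` object, or its `top_models` list.
#' @param cfg an [fs_config()].
#' @param protocol optional pre-built protocol; defaults to one derived from
#'   `cfg$seed` (sharing the seed with the model-selection stage reproduces
#'   the same split).
#' @param verbose print one summary line per generation.
#' @return A `ga_feature_selection` object: `best_mask` (named logical),
#'   `best_model`, `best_score`, `holdout` (one-row metric tibble), `history`,
#'   `audit`, `protocol`, `cfg`.
#' @export
run_feature_selection <- function(data,
                                  models,
                                  cfg = fs_config(),
                                  protocol = NULL,
                                  verbose = FALSE) {
  if (inherits(models, "ga_model_selection")) models <- models$top_models
  if (length(models) == 0) abort("no models supplied")
  ds <- dataset_matrix(data)
  d <- ncol(ds$x)
  if (cfg$min_active > d) abort("min_active exceeds the number of features")
  if (is.null(protocol)) {
    protocol <- make_eval_protocol(ds$y, seed = cfg$seed)
  }
  trained <- 0L
  decimations <- 0L
  best_history <- numeric(0)
  best_active_history <- integer(0)
  history <- vector("list", cfg$generations)
  # best-ever under (score desc, n_active asc, discovery asc)
  best <- list(score = -Inf, n_active = Inf, bits = NULL, model_index = NA_integer_)
  discovered <- 0L

  with_seed(stage_seed(cfg$seed, "ga_features"), {
    pop <- t(vapply(seq_len(cfg$population_size),
                    function(i) random_feature_genome(d, cfg$min_active),
                    logical(d)))
    strategy <- rep("random", cfg$population_size)

    for (gen in seq_len(cfg$generations)) {
      score <- numeric(nrow(pop))
      n_active <- integer(nrow(pop))
      for (i in seq_len(nrow(pop))) {
        ft <- feature_fitness(pop[i, ], models, ds, protocol, cfg$fitness_mode)
        score[i] <- ft$score
        n_active[i] <- ft$n_active
        trained <- trained + ft$trained
        discovered <- discovered + 1L
        if (ft$score > best$score + 1e-12 ||
            (abs(ft$score - best$score) <= 1e-12 && ft$n_active < best$n_active)) {
          best <- list(score = ft$score, n_active = ft$n_active,
                       bits = pop[i, ], model_index = ft$model_index,
                       discovered = discovered)
        }
      }
      ord <- order(-score, n_active)  # stable; later ties keep discovery order
      pop <- pop[ord, , drop = FALSE]
      score <- score[ord]
      n_active <- n_active[ord]
      best_history <- c(best_history, score[1])
      best_active_history <- c(best_active_history, best$n_active)
      strat_counts <- table(factor(strategy,
        levels = c("selection", "crossover", "mutation", "random", "survivor")))
      history[[gen]] <- tibble::tibble(
        generation = gen,
        best_fitness = score[1],
        best_n_active = n_active[1],
        median_fitness = median(score),
        n_individuals = nrow(pop),
        n_selection = strat_counts[["selection"]],
        n_crossover = strat_counts[["crossover"]],
        n_mutation = strat_counts[["mutation"]],
        n_random = strat_counts[["random"]],
        n_survivor = strat_counts[["survivor"]],
        decimated = FALSE
      )
      if (verbose) {
        message(sprintf("[feature-selection] gen %3d  best %.4f (%d active)  median %.4f",
                        gen, score[1], n_active[1], median(score)))
      }
      if (gen < cfg$generations) {
        stagnant <- check_perturbation(best_history, cfg$perturbation_patience) &&
          check_perturbation(best_active_history, cfg$perturbation_patience)
        if (stagnant) {
          survivor <- pop[1, , drop = FALSE]
          rest <- t(vapply(seq_len(cfg$population_size - 1L),
                           function(i) random_feature_genome(d, cfg$min_active),
                           logical(d)))
          pop <- rbind(survivor, rest)
          rownames(pop) <- NULL
          strategy <- c("survivor", rep("random", nrow(rest)))
          decimations <- decimations + 1L
          best_history <- best_history[length(best_history)]
          best_active_history <- best_active_history[length(best_active_history)]
          history[[gen]]$decimated <- TRUE
        } else {
          nxt <- next_generation_features(pop, cfg)
          pop <- nxt$pop
          strategy <- nxt$strategy
        }
      }
    }
  })

  best_mask <- stats::setNames(as.logical(best$bits), ds$feature_names)
  best_model <- models[[best$model_index]]
  holdout <- holdout_metrics(best_model$config, ds, protocol, mask = best_mask)

  structure(list(
    best_mask = best_mask,
    best_model = best_model,
    best_score = best$score,
    n_active = best$n_active,
    holdout = holdout,
    history = dplyr::bind_rows(history),
    audit = list(
      trained_models = trained,
      decimations = decimations,
      population_size = cfg$population_size,
      generations = cfg$generations,
      quotas = cfg$quotas,
      fitness_mode = cfg$fitness_mode
    ),
    protocol = protocol,
    cfg = cfg,
    feature_names = ds$feature_names
  ), class = "ga_feature_selection")
}

#' @export
print.ga_feature_selection <- function(x, ...) {
  cat(sprintf(
    "Feature selection: %d generations x %d individuals (%d models trained, %d decimation events)\n",
    x$audit$generations, x$audit$population_size,
    x$audit$trained_models, x$audit$decimations
  ))
  cat(sprintf("Best subset: %d of %d features, fitness %.4f, holdout AUC %.4f\n",
              x$n_active, length(x$best_mask), x$best_score, x$holdout$auc))
  invisible(x)
}
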