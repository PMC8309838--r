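#' Configuration of the model-selection genetic algorithm
#'
#' Defaults follow the study design: populations of 140 individuals evolved
#' for 30 generations, with per-generation reproduction quotas of 10 elites
#' carried by selection, 40 crossover children, 20 asexual fine-tuning
#' variants, 10 mutants and 60 fresh random genomes. A decimation
#' ("perturbation") event keeps only the strongest individual and regenerates
#' the rest whenever the best fitness has been flat for
#' `perturbation_patience` consecutive generations.
#'
#' @param population_size individuals per generation.
#' @param generations number of generations.
#' @param quotas named vector `selection`, `crossover`, `asexual`, `mutation`,
#'   `random`; must sum to `population_size`.
#' @param perturbation_patience flat-fitness generations before decimation.
#' @param seed run-level seed; all randomness of a run derives from it.
#' @param cache if `TRUE`, re-use fitness values of previously seen canonical
#'   configurations instead of re-training. Off by default, so the audited
#'   trained-model count is exactly `population_size * generations`.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 140,
                      generations = 30,
                      quotas = c(selection = 10, crossover = 40, asexual = 20,
                                 mutation = 10, random = 60),
                      perturbation_patience = 10,
                      seed = 1,
                      cache = FALSE) {
  quotas <- quotas[c("selection", "crossover", "asexual", "mutation", "random")]
  if (anyNA(quotas) || any(quotas < 0)) {
    abort("quotas must name selection, crossover, asexual, mutation, random (all >= 0)")
  }
  if (sum(quotas) != population_size) {
    abort(sprintf("quotas sum to %d but population_size is %d",
                  sum(quotas), population_size))
  }
  stopifnot(is_count(population_size), is_count(generations),
            is_count(perturbation_patience))
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 quotas = quotas,
                 perturbation_patience = as.integer(perturbation_patience),
                 seed = as.integer(seed), cache = isTRUE(cache)),
            class = "ga_config")
}

#' Random initial population of model genomes
#'
#' @param n number of genomes.
#' @param space a [build_parameter_space()] object.
#' @param seed integer seed.
#' @return Integer matrix, one genome per row, columns in [param_names()] order.
#' @export
init_population <- function(n, space, seed = 1) {
  stopifnot(is_count(n))
  with_seed(seed, {
    pop <- t(vapply(seq_len(n), function(i) random_model_genome(space),
                    integer(length(param_names()))))
    colnames(pop) <- param_names()
    pop
  })
}

random_population <- function(n, space) {
  pop <- t(vapply(seq_len(n), function(i) random_model_genome(space),
                  integer(length(param_names()))))
  colnames(pop) <- param_names()
  pop
}

#' Balanced uniform crossover of two model genomes
#'
#' Each child receives exactly half of its six genes from each parent, at
#' randomly chosen positions; the second child takes the complementary
#' assignment.
#'
#' @param p1,p2 parent genomes (integer vectors of six indices).
#' @return List of two children.
#' @export
crossover_models <- function(p1, p2) {
  n <- length(p1)
  from_p1 <- sample.int(n, n %/% 2)
  c1 <- p2; c1[from_p1] <- p1[from_p1]
  c2 <- p1; c2[from_p1] <- p2[from_p1]
  list(c1, c2)
}

#' Asexual fine-tuning variants of ranked parents
#'
#' Walks the ranked parents in order; for each parent, each gene in
#' [param_names()] order emits an index-minus-one and an index-plus-one
#' variant (out-of-bounds neighbours are skipped, not wrapped, since the
#' candidate lists are ordered scales), until `quota` genomes are collected.
#'
#' @param ranked_pop ranked genome matrix (best first).
#' @param quota number of variants to emit.
#' @param space a [build_parameter_space()] object.
#' @return Integer matrix of `quota` genomes.
#' @export
asexual_variants <- function(ranked_pop, quota, space) {
  out <- matrix(NA_integer_, nrow = quota, ncol = length(param_names()),
                dimnames = list(NULL, param_names()))
  if (quota == 0) return(out)
  got <- 0L
  repeat {
    for (r in seq_len(nrow(ranked_pop))) {
      parent <- ranked_pop[r, ]
      for (g in seq_along(parent)) {
        len <- length(space[[param_names()[g]]])
        for (step in c(-1L, 1L)) {
          idx <- parent[g] + step
          if (idx < 1L || idx > len) next
          v <- parent
          v[g] <- idx
          got <- got + 1L
          out[got, ] <- v
          if (got == quota) return(out)
        }
      }
    }
    # All parents exhausted before the quota (only possible for tiny spaces);
    # start over from the top-ranked parent.
  }
}

#' Single-gene mutation of a model genome
#'
#' Sets one randomly chosen gene to a different random in-bounds index; genes
#' whose candidate list has a single value cannot change and are excluded.
#'
#' @param genome integer genome.
#' @param space a [build_parameter_space()] object.
#' @return Mutated genome at Hamming distance 1 from the input.
#' @export
mutate_model <- function(genome, space) {
  lens <- vapply(param_names(), function(p) length(space[[p]]), integer(1))
  mutable <- which(lens > 1L)
  if (length(mutable) == 0) return(genome)
  g <- if (length(mutable) == 1) mutable else sample(mutable, 1)
  choices <- setdiff(seq_len(lens[g]), genome[g])
  genome[g] <- if (length(choices) == 1) choices else sample(choices, 1)
  genome
}

#' Produce the next generation from a ranked population
#'
#' Assembles, in fixed order: `selection` elite copies (top ranks), `crossover`
#' children of couples of two distinct elites drawn at random per pair,
#' `asexual` plus/minus-one variants of the top-ranked parents, `mutation`
#' single-gene mutants (one from the three best, one from the three worst,
#' the rest from uniformly random members) and `random` fresh genomes.
#'
#' @param ranked_pop genome matrix sorted by fitness, best first.
#' @param cfg a [ga_config()].
#' @param space a [build_parameter_space()] object.
#' @return List with `pop` (new genome matrix) and `strategy` (per-row label).
#' @export
next_generation_models <- function(ranked_pop, cfg, space) {
  q <- cfg$quotas
  n <- nrow(ranked_pop)
  elite_n <- min(q[["selection"]], n)
  parts <- list()
  strat <- character(0)

  elites <- ranked_pop[seq_len(elite_n), , drop = FALSE]
  parts$selection <- elites
  strat <- c(strat, rep("selection", nrow(elites)))

  n_children <- q[["crossover"]]
  kids <- matrix(NA_integer_, n_children, ncol(ranked_pop))
  i <- 1L
  while (i <= n_children) {
    couple <- if (nrow(elites) > 1) sample.int(nrow(elites), 2) else c(1L, 1L)
    ch <- crossover_models(elites[couple[1], ], elites[couple[2], ])
    kids[i, ] <- ch[[1]]
    if (i + 1L <= n_children) kids[i + 1L, ] <- ch[[2]]
    i <- i + 2L
  }
  parts$crossover <- kids
  strat <- c(strat, rep("crossover", n_children))

  parts$asexual <- asexual_variants(ranked_pop, q[["asexual"]], space)
  strat <- c(strat, rep("asexual", q[["asexual"]]))

  n_mut <- q[["mutation"]]
  if (n_mut > 0) {
    picks <- integer(n_mut)
    picks[1] <- sample.int(min(3L, n), 1)                     # among the best
    if (n_mut >= 2) picks[2] <- n - sample.int(min(3L, n), 1) + 1L  # among the worst
    if (n_mut >= 3) picks[3:n_mut] <- sample.int(n, n_mut - 2L, replace = TRUE)
    muts <- t(vapply(picks, function(p) mutate_model(ranked_pop[p, ], space),
                     integer(ncol(ranked_pop))))
    parts$mutation <- muts
    strat <- c(strat, rep("mutation", n_mut))
  }

  if (q[["random"]] > 0) {
    parts$random <- random_population(q[["random"]], space)
    strat <- c(strat, rep("random", q[["random"]]))
  }

  pop <- do.call(rbind, parts)
  colnames(pop) <- param_names()
  rownames(pop) <- NULL
  list(pop = pop, strategy = strat)
}

#' Has the best fitness stagnated long enough to trigger a perturbation?
#'
#' @param best_history numeric vector of best fitness per generation so far.
#' @param patience number of consecutive flat generations required.
#' @return `TRUE` when the last `patience` entries are equal within 1e-9.
#' @export
check_perturbation <- function(best_history, patience) {
  if (length(best_history) < patience) return(FALSE)
  recent <- tail(best_history, patience)
  all(abs(diff(recent)) < 1e-9)
}

# Decimation: only the strongest individual survives, the rest are regenerated.
apply_decimation <- function(ranked_pop, cfg, space) {
  survivor <- ranked_pop[1, , drop = FALSE]
  rest <- random_population(cfg$population_size - 1L, space)
  pop <- rbind(survivor, rest)
  colnames(pop) <- param_names()
  rownames(pop) <- NULL
  list(pop = pop, strategy = c("survivor", rep("random", nrow(rest))))
}

#' Evolve SVM configurations: the bucket-of-models stage
#'
#' Runs the model-selection genetic algorithm on a feature table. Every
#' individual of every generation is evaluated (one model training each, so
#' the audited count equals `population_size * generations` unless caching is
#' enabled), fitness being the mean ROC AUC over the protocol's inner
#' cross-validation folds. Returns the ten best distinct canonical
#' configurations seen anywhere in the run.
#'
#' @param data feature table (see [dataset_matrix()]).
#' @param cfg a [ga_config()].
#' @param space a [build_parameter_space()] object.
#' @param n_top number of distinct best configurations to return (default 10).
#' @param protocol optional pre-built [make_eval_protocol()]; by default one is
#'   derived from `cfg$seed`.
#' @param verbose print one summary line per generation.
#' @return A `ga_model_selection` object: `top_models` (list of
#'   `model_config`s with fitness), `history` (per-generation tibble), `audit`
#'   (trained-model counter, per-strategy counts, decimation events),
#'   `protocol`, `cfg`.
#' @examples
#' \donttest{
#' tab <- synth_feature_table(n_exams = 40, n_features = 8, n_informative = 3,
#'                            seed = 7)$table
#' fit <- run_model_selection(tab, ga_config(population_size = 10,
#'                                           generations = 3,
#'   quotas = c(selection = 2, crossover = 2, asexual = 2, mutation = 2,
#'              random = 2), seed = 7))
#' glance(fit)
#' }
#' @export
run_model_selection <- function(data,
                               cfg = ga_config(),
                               space = build_parameter_space(),
                               n_top = 10,
                               protocol = NULL,
                               verbose = FALSE) {
  ds <- dataset_matrix(data)
  if (is.null(protocol)) {
    protocol <- make_eval_protocol(ds$y, seed = cfg$seed)
  }
  archive <- new.env(parent = emptyenv())
  archive_order <- character(0)
  cache_env <- if (cfg$cache) new.env(parent = emptyenv()) else NULL
  trained <- 0L
  decimations <- 0L
  best_history <- numeric(0)
  history <- vector("list", cfg$generations)

  with_seed(stage_seed(cfg$seed, "ga_model"), {
    pop <- random_population(cfg$population_size, space)
    strategy <- rep("random", cfg$population_size)

    for (gen in seq_len(cfg$generations)) {
      fitness <- numeric(nrow(pop))
      for (i in seq_len(nrow(pop))) {
        config <- decode_genome(pop[i, ], space)
        key <- canonical_config(config, space)
        if (!is.null(cache_env) && !is.null(cache_env[[key]])) {
          fitness[i] <- cache_env[[key]]
        } else {
          res <- evaluate_config(config, ds, protocol)
          fitness[i] <- res$fitness
          trained <- trained + 1L
          if (!is.null(cache_env)) cache_env[[key]] <- res$fitness
        }
        if (is.null(archive[[key]]) || fitness[i] > archive[[key]]$fitness) {
          if (is.null(archive[[key]])) archive_order <- c(archive_order, key)
          archive[[key]] <- list(config = config, fitness = fitness[i], key = key)
        }
      }
      ord <- order(-fitness)  # stable: ties keep assembly (discovery) order
      pop <- pop[ord, , drop = FALSE]
      fitness <- fitness[ord]
      best_history <- c(best_history, fitness[1])
      strat_counts <- table(factor(strategy,
        levels = c("selection", "crossover", "asexual", "mutation", "random",
                   "survivor")))
      history[[gen]] <- tibble::tibble(
        generation = gen,
        best_fitness = fitness[1],
        median_fitness = median(fitness),
        n_individuals = nrow(pop),
        n_selection = strat_counts[["selection"]],
        n_crossover = strat_counts[["crossover"]],
        n_asexual = strat_counts[["asexual"]],
        n_mutation = strat_counts[["mutation"]],
        n_random = strat_counts[["random"]],
        n_survivor = strat_counts[["survivor"]],
        decimated = FALSE
      )
      if (verbose) {
        message(sprintf("[model-selection] gen %3d  best %.4f  median %.4f",
                        gen, fitness[1], median(fitness)))
      }
      if (gen < cfg$generations) {
        if (check_perturbation(best_history, cfg$perturbation_patience)) {
          nxt <- apply_decimation(pop, cfg, space)
          decimations <- decimations + 1L
          best_history <- best_history[length(best_history)]  # reset counter
          history[[gen]]$decimated <- TRUE
        } else {
          nxt <- next_generation_models(pop, cfg, space)
        }
        pop <- nxt$pop
        strategy <- nxt$strategy
      }
    }
  })

  entries <- lapply(archive_order, function(k) archive[[k]])
  fit_vals <- vapply(entries, function(e) e$fitness, numeric(1))
  ord <- order(-fit_vals)  # stable: ties broken by discovery order
  top <- entries[head(ord, n_top)]

  structure(list(
    top_models = top,
    history = dplyr::bind_rows(history),
    audit = list(
      trained_models = trained,
      decimations = decimations,
      population_size = cfg$population_size,
      generations = cfg$generations,
      quotas = cfg$quotas
    ),
    protocol = protocol,
    cfg = cfg,
    space = space,
    feature_names = ds$feature_names
  ), class = "ga_model_selection")
}

#' @export
print.ga_model_selection <- function(x, ...) {
  cat(sprintf(
    "Bucket of models: %d generations x %d individuals (%d models trained, %d decimation events)\n",
    x$audit$generations, x$audit$population_size,
    x$audit$trained_models, x$audit$decimations
  ))
  cat(sprintf("Best fitness (mean CV AUC): %.4f\n", x$top_models[[1]]$fitness))
  cat(sprintf("Top configuration: %s\n", x$top_models[[1]]$key))
  invisible(x)
}
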