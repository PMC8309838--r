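test_that("cutoff crossover swaps head and tail segments", {
  p1 <- rep(TRUE, 18)
  p2 <- rep(FALSE, 18)
  ch <- crossover_bits(p1, p2, cutoff = 6)
  expect_equal(sum(ch[[1]]), 6)   # first 6 from p1, rest from p2
  expect_equal(sum(ch[[2]]), 12)  # first 6 from p2, rest from p1
  expect_equal(ch[[1]], c(rep(TRUE, 6), rep(FALSE, 12)))
  expect_equal(ch[[2]], c(rep(FALSE, 6), rep(TRUE, 12)))
  # identical parents reproduce themselves
  set.seed(1)
  p <- runif(18) > 0.5
  ch <- crossover_bits(p, p, cutoff = 7)
  expect_equal(ch[[1]], p)
  expect_equal(ch[[2]], p)
  expect_error(crossover_bits(p1, p2, cutoff = 18), "cutoff")
})

test_that("children below the activity floor are repaired", {
  p1 <- c(rep(TRUE, 3), rep(FALSE, 15))
  p2 <- rep(FALSE, 18)
  set.seed(2)
  ch <- crossover_bits(p1, p2, cutoff = 4, min_active = 2)
  # child 2 would be all-FALSE without repair
  expect_gte(sum(ch[[2]]), 2)
})

test_that("bit mutation flips exactly one bit and honours the floor", {
  set.seed(3)
  g <- runif(30) > 0.5
  pos <- integer(1000)
  for (i in 1:1000) {
    m <- mutate_bit(g, min_active = 1)
    d <- which(m != g)
    expect_length(d, 1)
    pos[i] <- d
  }
  chi <- stats::chisq.test(table(factor(pos, levels = 1:30)))
  expect_gt(chi$p.value, 0.01)
  # a genome at the floor can only activate (or deactivate nothing)
  floor_g <- c(TRUE, rep(FALSE, 9))
  for (i in 1:50) {
    m <- mutate_bit(floor_g, min_active = 1)
    expect_equal(sum(m != floor_g), 1)
    expect_gte(sum(m), 1)
    expect_true(sum(m) == 2)  # the only legal moves are activations
  }
})

test_that("fitness of the all-ones genome equals a direct evaluation", {
  synth <- synth_feature_table(n_exams = 40, n_features = 8, n_informative = 3,
                               seed = 41)
  ds <- dataset_matrix(synth$table)
  prot <- make_eval_protocol(ds$y, seed = 7)
  space <- build_parameter_space()
  cfg <- decode_genome(c(3L, 12L, 1L, 3L, 1L, 1L), space)
  models <- list(list(config = cfg, fitness = NA, key = canonical_config(cfg, space)))
  ft <- feature_fitness(rep(TRUE, 8), models, ds, prot)
  direct <- evaluate_config(cfg, ds, prot)
  expect_equal(ft$score, direct$fitness)
  expect_equal(ft$n_active, 8L)
  expect_equal(ft$trained, 1L)
})

test_that("signal-bearing genomes outscore noise-only genomes", {
  synth <- synth_feature_table(n_exams = 80, n_features = 10, n_informative = 5,
                               effect_size = 1.5, seed = 43)
  # place informative columns at known positions by construction
  informative <- match(synth$informative, setdiff(names(synth$table),
                                                  c("exam_id", "class")))
  ds <- dataset_matrix(synth$table)
  prot <- make_eval_protocol(ds$y, seed = 11)
  space <- build_parameter_space()
  cfg <- decode_genome(c(3L, 12L, 1L, 3L, 1L, 1L), space)
  models <- list(list(config = cfg, fitness = NA, key = "m"))
  signal <- rep(FALSE, 10); signal[informative] <- TRUE
  noise <- !signal
  s1 <- feature_fitness(signal, models, ds, prot)$score
  s0 <- feature_fitness(noise, models, ds, prot)$score
  expect_gt(s1, s0)
})

test_that("model_set_max trains every model and takes the best score", {
  synth <- synth_feature_table(n_exams = 40, n_features = 6, n_informative = 2,
                               seed = 47)
  ds <- dataset_matrix(synth$table)
  prot <- make_eval_protocol(ds$y, seed = 13)
  space <- build_parameter_space()
  cfgs <- list(decode_genome(c(3L, 12L, 1L, 3L, 1L, 1L), space),
               decode_genome(c(3L, 30L, 20L, 3L, 2L, 2L), space))
  models <- lapply(cfgs, function(c) list(config = c, fitness = NA, key = "k"))
  bits <- rep(TRUE, 6)
  ft <- feature_fitness(bits, models, ds, prot, fitness_mode = "model_set_max")
  expect_equal(ft$trained, 2L)
  singles <- vapply(models, function(m)
    feature_fitness(bits, list(m), ds, prot)$score, numeric(1))
  expect_equal(ft$score, max(singles))
})

test_that("feature-selection runs are reproducible, respect the floor and prefer smaller subsets", {
  synth <- synth_feature_table(n_exams = 40, n_features = 12, n_informative = 4,
                               effect_size = 2, seed = 53)
  tab <- synth$table
  ms <- run_model_selection(tab, tiny_ms_cfg(pop = 10, gens = 2, seed = 3))
  cfg <- tiny_fs_cfg(pop = 10, gens = 5, seed = 3)
  f1 <- run_feature_selection(tab, ms, cfg, protocol = ms$protocol)
  f2 <- run_feature_selection(tab, ms, cfg, protocol = ms$protocol)
  expect_identical(f1$best_mask, f2$best_mask)
  expect_identical(f1$history, f2$history)
  expect_gte(sum(f1$best_mask), cfg$min_active)
  expect_lte(f1$n_active, 12)
  # audited trainings: one per individual per generation in top_model mode
  expect_equal(f1$audit$trained_models, 10 * 5)
  # best-so-far fitness never decreases
  expect_true(all(diff(f1$history$best_fitness) >= -1e-9))
  expect_error(fs_config(population_size = 140,
                         quotas = c(selection = 20, crossover = 40,
                                    mutation = 6, random = 73)),
               "sum")
})

test_that("a perfectly separable column makes the returned subset small", {
  # one column separates the classes completely; with ties broken towards
  # fewer active genes the search should not return a large subset
  set.seed(61)
  x <- matrix(rnorm(40 * 8), 40, 8)
  lab <- rep(c("cancer", "no_cancer"), each = 20)
  x[lab == "cancer", 4] <- x[lab == "cancer", 4] + 10
  df <- as.data.frame(x); names(df) <- sprintf("f%d", 1:8); df$class <- lab
  tab <- tibble::as_tibble(df)
  ms <- run_model_selection(tab, tiny_ms_cfg(pop = 10, gens = 2, seed = 5))
  fs <- run_feature_selection(tab, ms, tiny_fs_cfg(pop = 20, gens = 10, seed = 5,
    quotas = c(selection = 4, crossover = 6, mutation = 2, random = 8)),
    protocol = ms$protocol)
  expect_true(fs$best_mask[["f4"]])
  expect_lte(fs$n_active, 4)
  expect_equal(fs$best_score, 1)
})
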