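space <- build_parameter_space()

test_that("initial populations are seeded, valid and marginally uniform", {
  p1 <- init_population(140, space, seed = 3)
  p2 <- init_population(140, space, seed = 3)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(140, 6))
  lens <- vapply(param_names(), function(p) length(space[[p]]), integer(1))
  for (j in 1:6) {
    expect_true(all(p1[, j] >= 1 & p1[, j] <= lens[j]))
  }
  big <- init_population(1000, space, seed = 4)
  chi <- stats::chisq.test(table(factor(big[, "kernel"], levels = 1:3)))
  expect_gt(chi$p.value, 0.01)
})

test_that("crossover gives each child exactly half of each parent's genes", {
  set.seed(2)
  p1 <- rep(1L, 6)
  lens <- vapply(param_names(), function(p) length(space[[p]]), integer(1))
  p2 <- lens  # all-max-index
  for (i in 1:50) {
    ch <- crossover_models(p1, p2)
    expect_equal(sum(ch[[1]] == 1L), 3)
    expect_equal(sum(ch[[2]] == 1L), 3)
    # complementary assignment
    expect_true(all((ch[[1]] == p1) != (ch[[2]] == p1)))
  }
  # identical parents reproduce themselves
  ch <- crossover_models(p1, p1)
  expect_equal(ch[[1]], p1)
  expect_equal(ch[[2]], p1)
  # every child gene comes from a same-position parent gene
  set.seed(3)
  a <- thermoga:::random_model_genome(space)
  b <- thermoga:::random_model_genome(space)
  ch <- crossover_models(a, b)
  for (child in ch) expect_true(all(child == a | child == b))
})

test_that("asexual variants walk the plus/minus-one neighbourhood in rank order", {
  parent <- c(tolerance = 4L, gamma = 6L, coef0 = 10L, nu = 3L, degree = 2L,
              kernel = 2L)
  pop <- rbind(parent, parent + 1L)
  out <- asexual_variants(pop, 12, space)
  # first 12 variants come from the rank-1 parent, one gene changed by +/-1
  for (i in 1:12) {
    diffpos <- which(out[i, ] != parent)
    expect_length(diffpos, 1)
    expect_equal(unname(abs(out[i, diffpos] - parent[diffpos])), 1L)
  }
  # gamma at position 6 spawns neighbours 5 and 7
  gvars <- out[out[, "gamma"] != 6L, "gamma"]
  expect_setequal(as.integer(gvars), c(5L, 7L))
  # quota beyond one parent's neighbourhood continues with the next rank
  out20 <- asexual_variants(pop, 20, space)
  from_second <- out20[13:20, , drop = FALSE]
  for (i in seq_len(nrow(from_second))) {
    expect_equal(sum(from_second[i, ] != pop[2, ]), 1)
  }
  # boundary genes only emit the in-bounds neighbour
  low <- matrix(rep(1L, 6), 1, dimnames = list(NULL, param_names()))
  v <- asexual_variants(low, 6, space)
  expect_true(all(v >= 1L))
  expect_equal(as.vector(colSums(v != matrix(1L, 6, 6, byrow = TRUE))),
               rep(1, 6))
})

test_that("mutation changes exactly one gene and covers positions uniformly", {
  set.seed(5)
  g <- thermoga:::random_model_genome(space)
  pos <- integer(1000)
  for (i in 1:1000) {
    m <- mutate_model(g, space)
    d <- which(m != g)
    expect_length(d, 1)
    pos[i] <- d
  }
  chi <- stats::chisq.test(table(factor(pos, levels = 1:6)))
  expect_gt(chi$p.value, 0.01)
})

test_that("mutation skips genes with a single allowed value", {
  tiny <- build_parameter_space(tolerance = 0.1)  # only one tolerance
  set.seed(6)
  g <- thermoga:::random_model_genome(tiny)
  for (i in 1:50) {
    m <- mutate_model(g, tiny)
    expect_equal(m[["tolerance"]], g[["tolerance"]])
    expect_equal(sum(m != g), 1)
  }
})

test_that("next generations respect the strategy quotas", {
  cfg <- ga_config(seed = 1)
  set.seed(9)
  pop <- thermoga:::random_population(140, space)
  nxt <- next_generation_models(pop, cfg, space)
  expect_equal(nrow(nxt$pop), 140)
  expect_equal(as.vector(table(factor(nxt$strategy,
    levels = c("selection", "crossover", "asexual", "mutation", "random")))),
    c(10, 40, 20, 10, 60))
  # elites are carried unchanged
  expect_equal(nxt$pop[1:10, ], pop[1:10, ])
  # all children valid
  lens <- vapply(param_names(), function(p) length(space[[p]]), integer(1))
  for (j in 1:6) expect_true(all(nxt$pop[, j] >= 1 & nxt$pop[, j] <= lens[j]))
  expect_error(ga_config(quotas = c(selection = 10, crossover = 40,
                                    asexual = 20, mutation = 10, random = 59)),
               "sum")
})

test_that("perturbation triggers on flat fitness and decimation keeps one survivor", {
  expect_true(check_perturbation(rep(0.8, 10), 10))
  expect_false(check_perturbation(seq(0.1, 0.9, length.out = 10), 10))
  expect_false(check_perturbation(rep(0.8, 9), 10))
  cfg <- ga_config(seed = 2)
  set.seed(3)
  pop <- thermoga:::random_population(140, space)
  dec <- thermoga:::apply_decimation(pop, cfg, space)
  expect_equal(nrow(dec$pop), 140)
  expect_equal(dec$pop[1, ], pop[1, ])
  expect_equal(dec$strategy[1], "survivor")
  expect_equal(sum(dec$strategy == "random"), 139)
})

test_that("small runs audit exactly population x generations trainings", {
  tab <- synth_feature_table(n_exams = 20, n_features = 6, n_informative = 2,
                             seed = 31)$table
  cfg <- ga_config(population_size = 2, generations = 2,
                   quotas = c(selection = 1, crossover = 0, asexual = 0,
                              mutation = 0, random = 1), seed = 13)
  fit <- run_model_selection(tab, cfg)
  expect_equal(fit$audit$trained_models, 4)
  expect_equal(nrow(fit$history), 2)
  expect_true(all(fit$history$n_individuals == 2))
})

test_that("runs are bit-reproducible and best fitness is non-decreasing", {
  tab <- synth_feature_table(n_exams = 30, n_features = 8, n_informative = 3,
                             seed = 17)$table
  cfg <- tiny_ms_cfg(pop = 10, gens = 5, seed = 23)
  f1 <- run_model_selection(tab, cfg)
  f2 <- run_model_selection(tab, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(lapply(f1$top_models, `[[`, "key"),
                   lapply(f2$top_models, `[[`, "key"))
  expect_true(all(diff(f1$history$best_fitness) >= -1e-9))
  # top models are distinct canonical configurations sorted by fitness
  keys <- vapply(f1$top_models, `[[`, character(1), "key")
  expect_false(anyDuplicated(keys) > 0)
  fits <- vapply(f1$top_models, `[[`, numeric(1), "fitness")
  expect_true(all(diff(fits) <= 1e-12))
})
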