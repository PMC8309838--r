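rbf_config <- function(space = build_parameter_space(),
                       gamma = 0.1, nu = 0.4) {
  structure(list(tolerance = 0.001, gamma = gamma, coef0 = 0, nu = nu,
                 degree = 3, kernel = "rbf"), class = "model_config")
}

separable_table <- function(n = 40, d = 5, gap = 8, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d)
  lab <- rep(c("cancer", "no_cancer"), length.out = n)
  x[lab == "cancer", 1] <- x[lab == "cancer", 1] + gap
  df <- as.data.frame(x)
  names(df) <- sprintf("f%d", seq_len(d))
  df$class <- lab
  tibble::as_tibble(df)
}

test_that("the protocol is a stratified, deterministic 70/30 split with 4 folds", {
  y <- rep(c("cancer", "no_cancer"), each = 30)
  p1 <- make_eval_protocol(y, seed = 5)
  p2 <- make_eval_protocol(y, seed = 5)
  expect_identical(p1, p2)
  expect_length(p1$test_idx, 18)
  expect_length(p1$train_idx, 42)
  # stratification: 9 holdout exams per class
  expect_equal(sum(y[p1$test_idx] == "cancer"), 9)
  # every fold contains both classes
  for (f in 1:4) {
    expect_setequal(unique(y[p1$train_idx][p1$fold == f]),
                    c("cancer", "no_cancer"))
  }
  p3 <- make_eval_protocol(y, seed = 6)
  expect_false(identical(p1$test_idx, p3$test_idx))
})

test_that("holdout AUC is 1 on well-separated classes", {
  tab <- separable_table()
  ds <- dataset_matrix(tab)
  prot <- make_eval_protocol(ds$y, seed = 1)
  res <- evaluate_config(rbf_config(), ds, prot)
  expect_false(res$failed)
  expect_equal(res$fitness, 1)
  hm <- holdout_metrics(rbf_config(), ds, prot)
  expect_equal(hm$auc, 1)
})

test_that("permuted labels give chance-level fitness", {
  set.seed(10)
  x <- matrix(rnorm(60 * 5), 60, 5)
  aucs <- replicate(20, {
    df <- as.data.frame(x)
    names(df) <- sprintf("f%d", 1:5)
    df$class <- sample(rep(c("cancer", "no_cancer"), each = 30))
    ds <- dataset_matrix(df)
    prot <- make_eval_protocol(ds$y, seed = sample.int(1e6, 1))
    evaluate_config(rbf_config(), ds, prot)$fitness
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("confusion arithmetic follows the standard definitions", {
  truth <- c(rep("cancer", 4), rep("no_cancer", 4))
  pred <- c("cancer", "cancer", "cancer", "no_cancer", rep("no_cancer", 4))
  cm <- thermoga:::confusion_metrics(truth, pred)
  expect_equal(cm$tp, 3); expect_equal(cm$fn, 1)
  expect_equal(cm$tn, 4); expect_equal(cm$fp, 0)
  expect_equal(cm$sens, 0.75)
  expect_equal(cm$spec, 1)
  expect_equal(cm$acc, 0.875)
  expect_equal(cm$f1, 0.857, tolerance = 1e-3)
})

test_that("the rank AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(3)
  for (i in 1:10) {
    scores <- rnorm(40)
    labels <- sample(rep(c("cancer", "no_cancer"), 20))
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("no_cancer", "cancer"),
      direction = "<", quiet = TRUE)))
    expect_equal(thermoga:::auc_score(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("unfittable configurations score fitness 0 instead of raising", {
  # nu above twice the minority fraction is infeasible for nu-SVC
  tab <- separable_table(n = 40)
  tab$class <- c(rep("cancer", 10), rep("no_cancer", 30))
  ds <- dataset_matrix(tab)
  prot <- make_eval_protocol(ds$y, seed = 1)
  bad <- rbf_config(); bad$nu <- 0.9
  res <- evaluate_config(bad, ds, prot)
  expect_true(res$failed)
  expect_equal(res$fitness, 0)
})

test_that("metrics stay within [0, 1] across random configurations", {
  space <- build_parameter_space()
  tab <- separable_table(n = 32, gap = 1)
  ds <- dataset_matrix(tab)
  prot <- make_eval_protocol(ds$y, seed = 2)
  set.seed(8)
  for (i in 1:10) {
    cfg <- decode_genome(thermoga:::random_model_genome(space), space)
    res <- evaluate_config(cfg, ds, prot)
    expect_gte(res$fitness, 0); expect_lte(res$fitness, 1)
    if (!res$failed) {
      hm <- holdout_metrics(cfg, ds, prot)
      expect_true(all(unlist(hm) >= 0 & unlist(hm) <= 1))
    }
  }
})

test_that("the percentile baseline selects the top-F columns", {
  synth <- synth_feature_table(n_exams = 60, n_features = 10, n_informative = 3,
                               effect_size = 2, seed = 21)
  tab <- synth$table
  mask <- percentile_baseline(tab, 0.5)
  expect_equal(sum(mask), 5)
  mask3 <- percentile_baseline(tab, 0.3)
  expect_equal(sum(mask3), 3)
  expect_setequal(names(which(mask3)), synth$informative)
  expect_true(all(percentile_baseline(tab, 1.0)))
  expect_error(percentile_baseline(tab, 0), "percentile")
})

test_that("the closed-form F scores equal aov", {
  synth <- synth_feature_table(n_exams = 30, n_features = 4, n_informative = 2,
                               seed = 5)
  ds <- dataset_matrix(synth$table)
  f <- thermoga:::anova_f_scores(ds$x, ds$y)
  for (j in 1:4) {
    ref <- summary(stats::aov(ds$x[, j] ~ ds$y))[[1]]$`F value`[1]
    expect_equal(unname(f[j]), ref, tolerance = 1e-9)
  }
})
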