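#' Split a feature table into matrix and labels
#'
#' Internal-facing helper that separates a feature table (one row per exam,
#' feature columns plus a `class` column, optionally an `exam_id` column) into
#' the numeric matrix and class factor the evaluator consumes.
#'
#' @param data a data frame with a `class` column (values `cancer` /
#'   `no_cancer`), optionally an `exam_id` column, all remaining columns
#'   numeric features.
#' @return List with elements `x` (matrix), `y` (factor), `feature_names`,
#'   `exam_id`.
#' @export
dataset_matrix <- function(data) {
  stopifnot(is.data.frame(data))
  if (!"class" %in% names(data)) abort("feature table must have a 'class' column")
  y <- as_class_factor(data$class)
  exam_id <- if ("exam_id" %in% names(data)) as.character(data$exam_id) else
    as.character(seq_len(nrow(data)))
  feat <- setdiff(names(data), c("class", "exam_id"))
  if (length(feat) == 0) abort("feature table has no feature columns")
  x <- as.matrix(as.data.frame(data)[, feat, drop = FALSE])
  storage.mode(x) <- "double"
  if (nrow(x) < 8) abort("feature table must have at least 8 rows")
  if (any(!is.finite(x))) abort("feature table contains non-finite values")
  if (nlevels(droplevels(y)) < 2) abort("both classes must be present")
  list(x = x, y = y, feature_names = feat, exam_id = exam_id)
}

#' Evaluation protocol: stratified holdout plus inner cross-validation
#'
#' Builds the split used for every fitness evaluation of a run: a stratified
#' 70/30 train/holdout split, and a stratified 4-fold partition of the training
#' part. The genetic algorithms score individuals by the mean ROC AUC over the
#' inner folds; the holdout part is touched only once, to report the final
#' metrics of the returned model. One protocol (hence one seed) is shared by
#' all individuals of a run so that fitness values are comparable.
#'
#' @param y class factor (or character vector) of labels.
#' @param holdout_fraction fraction of exams withheld from the evolutionary
#'   search (default 0.3).
#' @param cv_folds number of inner cross-validation folds (default 4).
#' @param seed integer seed fixing the split.
#' @return An `eval_protocol`: list with `train_idx`, `test_idx`, `fold`
#'   (fold id per training row), and the protocol parameters.
#' @export
make_eval_protocol <- function(y, holdout_fraction = 0.3, cv_folds = 4, seed = 1) {
  y <- as_class_factor(y)
  stopifnot(holdout_fraction > 0, holdout_fraction < 1, is_count(cv_folds))
  idx_by_class <- split(seq_along(y), y)
  with_seed(stage_seed(seed, "protocol"), {
    test_idx <- sort(unlist(lapply(idx_by_class, function(ix) {
      n_test <- round(length(ix) * holdout_fraction)
      sample(ix, n_test)
    }), use.names = FALSE))
    train_idx <- setdiff(seq_along(y), test_idx)
    fold <- integer(length(train_idx))
    for (cl in levels(y)) {
      pos <- which(y[train_idx] == cl)
      fold[pos] <- sample(rep_len(seq_len(cv_folds), length(pos)))
    }
    for (f in seq_len(cv_folds)) {
      cls <- unique(y[train_idx][fold != f])
      if (length(cls) < 2) {
        abort(sprintf("protocol error: fold %d leaves a single-class training set", f))
      }
      cls_in <- unique(y[train_idx][fold == f])
      if (length(cls_in) < 2) {
        abort(sprintf("protocol error: fold %d contains a single class", f))
      }
    }
    structure(
      list(train_idx = train_idx, test_idx = test_idx, fold = fold,
           holdout_fraction = holdout_fraction, cv_folds = cv_folds,
           seed = seed),
      class = "eval_protocol"
    )
  })
}

# Column standardisation from training statistics; zero-variance columns are
# left centred at 0 so binary-map features cannot blow up.
scale_fit <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(mu = mu, s = s)
}
scale_apply <- function(x, sc) {
  sweep(sweep(x, 2, sc$mu, "-"), 2, sc$s, "/")
}

kernel_map <- c(rbf = "radial", poly = "polynomial", sigmoid = "sigmoid")

# Fit a nu-SVM with the configuration's kernel-relevant parameters and return
# decision scores on new data, oriented so that larger means "cancer".
#
# The SMO termination criterion is floored at option "thermoga.tol_floor"
# (default 1e-5): tighter KKT gaps are numerically unattainable for unbounded
# kernels on small non-separable problems and only burn the solver's internal
# iteration budget without changing the classifier at reported precision.
# Genomes, canonical forms and grid counts keep the configured tolerance.
svm_decision <- function(config, x_train, y_train, x_new) {
  tol <- max(config$tolerance, getOption("thermoga.tol_floor", 1e-5))
  fit <- e1071::svm(
    x = x_train, y = y_train, scale = FALSE,
    type = "nu-classification",
    kernel = kernel_map[[config$kernel]],
    nu = config$nu, gamma = config$gamma, coef0 = config$coef0,
    degree = config$degree, tolerance = tol
  )
  pred <- predict(fit, x_new, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  score <- if (identical(first, POSITIVE_CLASS)) dv[, 1] else -dv[, 1]
  list(score = score, predicted = pred)
}

#' Evaluate one SVM configuration under the run protocol
#'
#' Computes the genetic-algorithm fitness of a configuration: the mean ROC AUC
#' over the protocol's stratified inner cross-validation folds, using only the
#' columns activated by `mask`. Configurations that cannot be fitted (e.g. a
#' `nu` infeasible for the class balance) receive fitness 0 rather than
#' raising, so the evolutionary search can discard them.
#'
#' @param config a `model_config` from [decode_genome()].
#' @param ds a dataset from [dataset_matrix()].
#' @param protocol an [make_eval_protocol()] object.
#' @param mask logical vector over feature columns (default all active).
#' @return List with `fitness` (mean CV AUC; 0 for unfittable configurations),
#'   `fold_auc`, and `failed`.
#' @export
evaluate_config <- function(config, ds, protocol, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, ncol(ds$x))
  mask <- as.logical(mask)
  if (length(mask) != ncol(ds$x)) abort("mask length must match feature count")
  if (!any(mask)) return(list(fitness = 0, fold_auc = rep(NA_real_, protocol$cv_folds), failed = TRUE))
  xt <- ds$x[protocol$train_idx, mask, drop = FALSE]
  yt <- ds$y[protocol$train_idx]
  fold_auc <- rep(NA_real_, protocol$cv_folds)
  for (f in seq_len(protocol$cv_folds)) {
    in_f <- protocol$fold == f
    sc <- scale_fit(xt[!in_f, , drop = FALSE])
    res <- tryCatch(
      svm_decision(config,
                   scale_apply(xt[!in_f, , drop = FALSE], sc), yt[!in_f],
                   scale_apply(xt[in_f, , drop = FALSE], sc)),
      error = function(e) NULL
    )
    if (is.null(res)) {
      return(list(fitness = 0, fold_auc = fold_auc, failed = TRUE))
    }
    fold_auc[f] <- auc_score(res$score, yt[in_f])
  }
  list(fitness = mean(fold_auc), fold_auc = fold_auc, failed = FALSE)
}

#' Final holdout metrics for a configuration
#'
#' Refits the configuration on the protocol's full training part (restricted to
#' the active columns) and scores the 30% holdout, reporting the five standard
#' metrics with `cancer` as the positive class.
#'
#' @inheritParams evaluate_config
#' @return A one-row tibble: `auc`, `f1`, `acc`, `sens`, `spec` (all in
#'   \eqn{[0, 1]}), plus the protocol descriptor as attribute `"protocol"`.
#' @export
holdout_metrics <- function(config, ds, protocol, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, ncol(ds$x))
  mask <- as.logical(mask)
  if (!any(mask)) abort("mask must activate at least one column")
  xt <- ds$x[protocol$train_idx, mask, drop = FALSE]
  xh <- ds$x[protocol$test_idx, mask, drop = FALSE]
  sc <- scale_fit(xt)
  res <- tryCatch(
    svm_decision(config, scale_apply(xt, sc), ds$y[protocol$train_idx],
                 scale_apply(xh, sc)),
    error = function(e) NULL
  )
  yh <- ds$y[protocol$test_idx]
  if (is.null(res)) {
    out <- tibble::tibble(auc = 0, f1 = 0, acc = 0, sens = 0, spec = 0)
  } else {
    cm <- confusion_metrics(yh, res$predicted)
    out <- tibble::tibble(
      auc = auc_score(res$score, yh),
      f1 = cm$f1, acc = cm$acc, sens = cm$sens, spec = cm$spec
    )
  }
  attr(out, "protocol") <- protocol
  out
}

#' Percentile baseline feature selection
#'
#' Non-evolutionary baseline: scores every feature column with the two-class
#' ANOVA F statistic and activates the top `ceiling(percentile * d)` columns.
#'
#' @param data a feature table (see [dataset_matrix()]).
#' @param percentile fraction of columns to keep, in (0, 1].
#' @return Named logical vector over the feature columns (the selection mask),
#'   with the per-column F scores attached as attribute `"scores"`.
#' @examples
#' tab <- synth_feature_table(n_exams = 40, n_features = 10, seed = 1)$table
#' mask <- percentile_baseline(tab, 0.3)
#' names(which(mask))
#' @export
percentile_baseline <- function(data, percentile) {
  stopifnot(percentile > 0, percentile <= 1)
  ds <- dataset_matrix(data)
  d <- ncol(ds$x)
  k <- ceiling(percentile * d)
  if (k < 1) abort("percentile selects zero columns")
  f <- anova_f_scores(ds$x, ds$y)
  keep <- head(order(f, decreasing = TRUE), k)
  mask <- stats::setNames(rep(FALSE, d), ds$feature_names)
  mask[keep] <- TRUE
  attr(mask, "scores") <- f
  mask
}

# Closed-form one-way ANOVA F for two (or more) groups, per column.
anova_f_scores <- function(x, y) {
  y <- droplevels(factor(y))
  n <- nrow(x)
  g <- nlevels(y)
  grand <- colMeans(x)
  ss_between <- numeric(ncol(x))
  ss_within <- numeric(ncol(x))
  for (cl in levels(y)) {
    xi <- x[y == cl, , drop = FALSE]
    ni <- nrow(xi)
    mi <- colMeans(xi)
    ss_between <- ss_between + ni * (mi - grand)^2
    ss_within <- ss_within + colSums(sweep(xi, 2, mi, "-")^2)
  }
  ms_between <- ss_between / (g - 1)
  ms_within <- ss_within / (n - g)
  f <- ms_between / ms_within
  f[ms_within < 1e-300] <- Inf
  f[ss_between < 1e-300] <- 0
  f
}
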