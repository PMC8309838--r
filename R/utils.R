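#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif sd var median predict quantile
#' @importFrom utils head tail
NULL

# Derive a reproducible sub-seed for a named stage from one run-level seed.
# Keeps every derived seed a valid 32-bit integer.
stage_seed <- function(seed, stage) {
  offset <- sum(utf8ToInt(stage)) * 7919L
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == as.integer(x) && x > 0
}

# Class labels used throughout: the positive (diseased) class first.
CLASS_LEVELS <- c("cancer", "no_cancer")
POSITIVE_CLASS <- "cancer"

as_class_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), CLASS_LEVELS)
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown class token(s): %s (allowed: %s)",
      paste(bad, collapse = ", "), paste(CLASS_LEVELS, collapse = ", ")
    ))
  }
  factor(labels, levels = CLASS_LEVELS)
}
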