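# The six named feature groups. A recipe lists per-breast extractor calls;
# a group vector is the left-breast fragment followed by the right-breast
# fragment (for every extractor in recipe order within each breast).

GROUP_NAMES <- c("fractals_wavelets_8ltp", "fractals_8ltp", "glcm",
                 "fractals_2ltp_glcm", "fractals_3ltp", "glcm_8ltp")

#' Feature group recipe
#'
#' Returns the recipe of one of the six named feature groups, with its
#' expected length: `fractals_wavelets_8ltp` (384 = 3 fractals x 8 wavelets x
#' 8 spectra x 2 breasts), `fractals_8ltp` (48), `glcm` (48 = 6 descriptors x
#' 4 directions x 2 breasts), `fractals_2ltp_glcm` (60, spectra 0 and 4 plus
#' GLCM), `fractals_3ltp` (18, spectra 0, 3 and 6) and `glcm_8ltp` (148 = 100
#' LTP histogram features plus GLCM).
#'
#' @param name group name, or a custom recipe list with elements `name`,
#'   `extractors` and `expected_length`.
#' @return A `feature_group` list.
#' @export
feature_group <- function(name) {
  if (is.list(name)) {
    stopifnot(!is.null(name$name), !is.null(name$extractors),
              !is.null(name$expected_length))
    return(structure(name, class = "feature_group"))
  }
  recipes <- list(
    fractals_wavelets_8ltp = list(
      extractors = list(list(fn = "wavelet_fractal", spectra = 0:7)),
      expected_length = 384L),
    fractals_8ltp = list(
      extractors = list(list(fn = "ltp_fractal", spectra = 0:7)),
      expected_length = 48L),
    glcm = list(
      extractors = list(list(fn = "glcm")),
      expected_length = 48L),
    fractals_2ltp_glcm = list(
      extractors = list(list(fn = "ltp_fractal", spectra = c(0L, 4L)),
                        list(fn = "glcm")),
      expected_length = 60L),
    fractals_3ltp = list(
      extractors = list(list(fn = "ltp_fractal", spectra = c(0L, 3L, 6L))),
      expected_length = 18L),
    glcm_8ltp = list(
      extractors = list(list(fn = "ltp_histogram"),
                        list(fn = "glcm")),
      expected_length = 148L)
  )
  if (!name %in% names(recipes)) {
    abort(sprintf("unknown feature group '%s' (known: %s)",
                  name, paste(GROUP_NAMES, collapse = ", ")))
  }
  structure(c(list(name = name), recipes[[name]]), class = "feature_group")
}

run_extractor <- function(ex, roi, t, k_max) {
  switch(ex$fn,
    wavelet_fractal = {
      if (any(ex$spectra < 0 | ex$spectra > 8)) abort("undefined spectrum index")
      wavelet_fractal_features(roi, t = t, spectra = ex$spectra, k_max = k_max)
    },
    ltp_fractal = {
      if (any(ex$spectra < 0 | ex$spectra > 8)) abort("undefined spectrum index")
      ltp_fractal_features(roi, t = t, spectra = ex$spectra, k_max = k_max)
    },
    glcm = glcm_features(roi),
    ltp_histogram = ltp_histogram_features(roi, t = t),
    abort(sprintf("unknown extractor '%s'", ex$fn))
  )
}

#' Compute one feature group for an exam
#'
#' Runs the group's extractors on both breasts and concatenates the fragments
#' in fixed (left, right) order. Column names carry breast and extractor
#' provenance (`l_`/`r_` prefix); the output length always equals the group's
#' expected length.
#'
#' @param pair a [roi_pair()].
#' @param group a group name or [feature_group()].
#' @param t LTP dead-zone threshold in degrees Celsius.
#' @param k_max Higuchi scale limit.
#' @return Named numeric vector of length `group$expected_length`.
#' @examples
#' pairs <- synth_roi_pairs(n_exams = 1, seed = 1)
#' length(compute_group(pairs[[1]], "fractals_3ltp"))  # 18
#' @export
compute_group <- function(pair, group, t = 0.1, k_max = 8L) {
  stopifnot(inherits(pair, "roi_pair"))
  if (!inherits(group, "feature_group")) group <- feature_group(group)
  frag <- function(roi, prefix) {
    v <- unlist(lapply(group$extractors, run_extractor,
                       roi = roi, t = t, k_max = k_max))
    stats::setNames(v, paste0(prefix, "_", names(v)))
  }
  out <- c(frag(pair$left, "l"), frag(pair$right, "r"))
  if (length(out) != group$expected_length) {
    abort(sprintf("group '%s' produced %d values, expected %d",
                  group$name, length(out), group$expected_length))
  }
  if (anyDuplicated(names(out))) abort("duplicate feature column names")
  out
}

#' Extract a feature table from labeled exams
#'
#' Computes one feature group for every exam and assembles the row-per-exam
#' table consumed by the evolutionary stages, with `exam_id` first and the
#' class label last. Row order follows input order.
#'
#' @param pairs list of labeled [roi_pair()] objects.
#' @param group a group name or [feature_group()].
#' @param t LTP dead-zone threshold.
#' @param k_max Higuchi scale limit.
#' @return A tibble with columns `exam_id`, the group's feature columns, and
#'   `class`.
#' @export
extract_table <- function(pairs, group, t = 0.1, k_max = 8L) {
  if (length(pairs) == 0) abort("empty exam list: no table to extract")
  if (!inherits(group, "feature_group")) group <- feature_group(group)
  labels <- vapply(pairs, function(p) {
    if (is.null(p$label)) abort(sprintf("exam %s is unlabeled", p$exam_id))
    p$label
  }, character(1))
  rows <- lapply(pairs, compute_group, group = group, t = t, k_max = k_max)
  nm <- names(rows[[1]])
  for (r in rows) {
    if (!identical(names(r), nm)) abort("inconsistent feature columns across exams")
  }
  mat <- do.call(rbind, rows)
  tibble::as_tibble(as.data.frame(mat)) |>
    dplyr::mutate(
      exam_id = vapply(pairs, function(p) p$exam_id, character(1)),
      class = labels, .before = 1
    ) |>
    dplyr::relocate("class", .after = dplyr::last_col())
}
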