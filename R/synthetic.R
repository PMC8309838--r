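# Seeded synthetic inputs with the statistical structure the method assumes:
# two-class ROI pairs whose diseased class carries a localized hot-spot
# asymmetry, and two-class Gaussian feature tables with a known informative
# subset.

#' Synthetic two-class breast ROI pairs
#'
#' Generates exams of paired breast temperature matrices: a uniform baseline
#' plus Gaussian sensor noise, with the `cancer` class adding a radially
#' decaying (2-D Gaussian) hot spot of amplitude `hotspot_amplitude` on one
#' randomly chosen breast. Defaults emulate a balanced static-thermography
#' screening set of 80 exams of 64x64 ROIs at a 33 degC skin baseline.
#' Ground-truth hot-spot parameters are attached to each cancer exam.
#'
#' @param n_exams number of exams (pairs).
#' @param class_balance fraction of `cancer` exams; the class counts are
#'   `round(n_exams * class_balance)` vs the rest.
#' @param shape image dimensions `c(rows, cols)` (at least 16x16).
#' @param baseline_temp skin baseline in degrees Celsius.
#' @param hotspot_amplitude peak excess temperature of the lesion (degC);
#'   0 gives exchangeable classes (a null benchmark).
#' @param hotspot_radius Gaussian radius of the lesion in pixels.
#' @param noise_sd sensor noise standard deviation (degC).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return List of labeled [roi_pair()] objects. Cancer exams carry an
#'   attribute `"hotspot"` (side, center, amplitude, radius).
#' @examples
#' pairs <- synth_roi_pairs(n_exams = 4, seed = 1)
#' table(vapply(pairs, function(p) p$label, character(1)))
#' @export
synth_roi_pairs <- function(n_exams = 80,
                            class_balance = 0.5,
                            shape = c(64, 64),
                            baseline_temp = 33,
                            hotspot_amplitude = 2,
                            hotspot_radius = 8,
                            noise_sd = 0.1,
                            seed = 1) {
  stopifnot(is_count(n_exams), class_balance > 0, class_balance < 1,
            hotspot_amplitude >= 0, hotspot_radius > 0, noise_sd >= 0)
  if (any(shape < 16)) abort("shape too small: need at least 16x16 for the texture stack")
  n_cancer <- round(n_exams * class_balance)
  labels <- c(rep("cancer", n_cancer), rep("no_cancer", n_exams - n_cancer))
  nr <- shape[1]; nc <- shape[2]
  with_seed(stage_seed(seed, "synth_rois"), {
    lapply(seq_len(n_exams), function(i) {
      mk <- function(side) {
        roi_matrix(matrix(baseline_temp + rnorm(nr * nc, sd = noise_sd), nr, nc),
                   side = side)
      }
      left <- mk("left"); right <- mk("right")
      hs <- NULL
      if (labels[i] == "cancer") {
        side <- sample(c("left", "right"), 1)
        cr <- sample(seq(nr %/% 4, 3 * nr %/% 4), 1)
        cc <- sample(seq(nc %/% 4, 3 * nc %/% 4), 1)
        bump <- hotspot_amplitude *
          exp(-(outer((seq_len(nr) - cr)^2, (seq_len(nc) - cc)^2, "+")) /
                (2 * hotspot_radius^2))
        if (side == "left") left$values <- left$values + bump
        else right$values <- right$values + bump
        hs <- list(side = side, center = c(cr, cc),
                   amplitude = hotspot_amplitude, radius = hotspot_radius)
      }
      p <- roi_pair(left, right, label = labels[i],
                    exam_id = sprintf("exam_%03d", i))
      attr(p, "hotspot") <- hs
      p
    })
  })
}

#' Synthetic two-class Gaussian feature table
#'
#' Class-conditional Gaussian features: a seeded random subset of
#' `n_informative` columns differs in mean between the classes by
#' `effect_size` pooled standard deviations; the remaining columns are pure
#' noise. The default benchmark (160 exams, 50 features, 10 informative,
#' effect 1.5) is separable enough that a reasonable classifier on the true
#' columns reaches holdout AUC above 0.9.
#'
#' @param n_exams number of rows.
#' @param n_features number of feature columns.
#' @param n_informative number of class-associated columns.
#' @param effect_size between-class mean shift in pooled-sd units.
#' @param class_balance fraction of `cancer` rows.
#' @param seed integer seed.
#' @return List with `table` (tibble: `exam_id`, features `f01`..., `class`)
#'   and `informative` (names of the ground-truth informative columns).
#' @examples
#' synth <- synth_feature_table(n_exams = 20, n_features = 6,
#'                              n_informative = 2, seed = 1)
#' synth$informative
#' @export
synth_feature_table <- function(n_exams = 160,
                                n_features = 50,
                                n_informative = 10,
                                effect_size = 1.5,
                                class_balance = 0.5,
                                seed = 1) {
  stopifnot(is_count(n_exams), is_count(n_features),
            n_informative >= 0, n_informative <= n_features,
            class_balance > 0, class_balance < 1, effect_size >= 0)
  n_cancer <- round(n_exams * class_balance)
  labels <- c(rep("cancer", n_cancer), rep("no_cancer", n_exams - n_cancer))
  fmt <- paste0("f%0", max(2, nchar(n_features)), "d")
  cols <- sprintf(fmt, seq_len(n_features))
  with_seed(stage_seed(seed, "synth_table"), {
    informative <- if (n_informative > 0) sort(sample(n_features, n_informative))
                   else integer(0)
    x <- matrix(rnorm(n_exams * n_features), n_exams, n_features)
    x[labels == "cancer", informative] <-
      x[labels == "cancer", informative] + effect_size
    colnames(x) <- cols
    tab <- tibble::as_tibble(as.data.frame(x)) |>
      dplyr::mutate(exam_id = sprintf("exam_%03d", seq_len(n_exams)),
                    class = labels, .before = 1) |>
      dplyr::relocate("class", .after = dplyr::last_col())
    list(table = tab, informative = cols[informative])
  })
}
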