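# Single-level 2-D Daubechies analysis (approximation band only).
#
# Scaling (decomposition lowpass) filters of the eight standard Daubechies
# families; standard published constants.
DB_FILTERS <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.2241438680420134, 0.8365163037378079,
          0.48296291314453416),
  db3 = c(0.03522629188570953, -0.08544127388202666, -0.13501102001025458,
          0.45987750211849154, 0.8068915093110925, 0.33267055295008263),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  db5 = c(0.0033357252854737712, -0.012580751999081999, -0.006241490212798274,
          0.07757149384004572, -0.032244869584638375, -0.24229488706638203,
          0.13842814590132074, 0.7243085284377729, 0.6038292697971896,
          0.16010239797419293),
  db6 = c(-0.0010773010853084796, 0.004777257510945511, 0.0005538422011614961,
          -0.03158203931748603, 0.027522865530305727, 0.09750160558732304,
          -0.12976686756726194, -0.22626469396543983, 0.31525035170919763,
          0.7511339080210954, 0.49462389039845306, 0.11154074335010947),
  db7 = c(0.00035371379997452024, -0.0018016407040474908, 0.0004295779729213665,
          0.01255099855609984, -0.01657454163066688, -0.03802993693501441,
          0.08061260915108308, 0.07130921926683026, -0.22403618499387498,
          -0.14390600392856498, 0.4697822874051931, 0.7291320908462351,
          0.3965393194819173, 0.07785205408500918),
  db8 = c(-0.00011747678412476953, 0.0006754494064505693,
          -0.00039174037337694705, -0.004870352993451574, 0.008746094047405777,
          0.013981027917398282, -0.044088253930794755, -0.017369301001807547,
          0.12874742662047847, 0.0004724845739132828, -0.2840155429615469,
          -0.015829105256349306, 0.5853546836542067, 0.6756307362972898,
          0.31287159091429995, 0.05441584224310401)
)

# Periodized lowpass filtering + dyadic downsampling of one signal.
# a[k] = sum_m h[m] * s[(2k - m) mod N]; a constant signal maps to a constant
# (times sum(h) = sqrt(2)), so flat maps stay flat after decomposition.
conv_down_periodic <- function(s, h) {
  n <- length(s)
  half <- n %/% 2L
  l <- length(h)
  out <- numeric(half)
  for (m in seq_len(l)) {
    idx <- ((2L * seq_len(half) - 1L - (m - 1L)) %% n) + 1L
    out <- out + h[m] * s[idx]
  }
  out
}

#' Single-level 2-D wavelet approximation band
#'
#' Periodized separable Daubechies analysis of a matrix: the lowpass filter is
#' applied with dyadic downsampling along rows, then along columns, returning
#' the approximation (LL) band. Odd dimensions are first padded to even by
#' replicating the last row/column.
#'
#' @param m numeric matrix.
#' @param family one of `"db1"` ... `"db8"`.
#' @return The approximation band, a matrix of roughly half the size in each
#'   dimension.
#' @export
dwt2_approx <- function(m, family = "db1") {
  h <- DB_FILTERS[[family]]
  if (is.null(h)) abort(sprintf("unknown wavelet family '%s'", family))
  if (nrow(m) %% 2L == 1L) m <- rbind(m, m[nrow(m), ])
  if (ncol(m) %% 2L == 1L) m <- cbind(m, m[, ncol(m)])
  lo_rows <- t(apply(m, 1, conv_down_periodic, h = h))
  if (nrow(m) == 1L) lo_rows <- matrix(lo_rows, nrow = 1L)
  approx <- apply(lo_rows, 2, conv_down_periodic, h = h)
  if (!is.matrix(approx)) approx <- matrix(approx, nrow = 1L)
  approx
}

#' Wavelet-fractal composite features of one breast ROI
#'
#' For each local ternary pattern spectrum map (spectra 0-7 by default) and
#' each Daubechies family db1-db8, the map (cropped to the mask bounding box)
#' is decomposed one level, the approximation band is flattened row-major,
#' and the three complexity estimators of [fractal_trio()] are applied:
#' 3 fractals x 8 wavelets x 8 spectra = 192 values per breast.
#'
#' @param roi a [roi_matrix()].
#' @param t LTP dead-zone threshold in degrees Celsius.
#' @param spectra spectrum indices to use (default 0:7).
#' @param wavelets Daubechies family names (default db1-db8).
#' @param k_max Higuchi scale limit.
#' @return Named numeric vector in (spectrum, wavelet, fractal) order, names
#'   `wf_s<k>_db<j>_<estimator>`.
#' @export
wavelet_fractal_features <- function(roi, t = 0.1, spectra = 0:7,
                                     wavelets = names(DB_FILTERS),
                                     k_max = 8L) {
  sm <- ltp_spectrum_maps(roi, t)
  out <- numeric(0)
  for (k in spectra) {
    key <- paste0("s", k)
    if (is.null(sm$maps[[key]])) abort(sprintf("undefined spectrum index %s", k))
    map <- crop_to_mask_bbox(sm$maps[[key]], sm$interior_mask)
    for (w in wavelets) {
      approx <- dwt2_approx(map, w)
      series <- as.vector(t(approx))  # row-major
      trio <- fractal_trio(series, k_max)
      names(trio) <- sprintf("wf_s%d_%s_%s", k, w, names(trio))
      out <- c(out, trio)
    }
  }
  out
}

# Fractal trio over raw (un-decomposed) spectrum maps, for the non-wavelet
# feature groups: 3 values per requested spectrum.
ltp_fractal_features <- function(roi, t = 0.1, spectra = 0:7, k_max = 8L) {
  sm <- ltp_spectrum_maps(roi, t)
  out <- numeric(0)
  for (k in spectra) {
    key <- paste0("s", k)
    if (is.null(sm$maps[[key]])) abort(sprintf("undefined spectrum index %s", k))
    map <- crop_to_mask_bbox(sm$maps[[key]], sm$interior_mask)
    trio <- fractal_trio(as.vector(t(map)), k_max)
    names(trio) <- sprintf("ltpfrac_s%d_%s", k, names(trio))
    out <- c(out, trio)
  }
  out
}
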