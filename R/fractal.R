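# One-dimensional complexity estimators applied to flattened texture maps.

#' Higuchi fractal dimension
#'
#' Curve-length estimator: for each scale k up to `k_max`, the mean normalized
#' length of the k-subsampled curves is computed, and the dimension is the
#' slope of log(L(k)) against log(1/k). A constant series has zero curve
#' length at every scale; the estimator then returns the sentinel 1.0 (the
#' dimension of a smooth line) instead of a non-finite value.
#'
#' @param x numeric series of length at least 32.
#' @param k_max maximum delay scale (default 8).
#' @return The estimated dimension (typically in \eqn{[1, 2]}).
#' @export
higuchi_fd <- function(x, k_max = 8L) {
  n <- length(x)
  stopifnot(n >= 32, k_max >= 2)
  lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      ni <- length(idx) - 1L
      if (ni < 1) { lm[m] <- NA_real_; next }
      lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (ni * k) / k
    }
    lk[k] <- mean(lm, na.rm = TRUE)
  }
  if (any(!is.finite(lk)) || any(lk <= 0)) return(1.0)
  stats::coef(stats::lm(log(lk) ~ log(1 / seq_len(k_max))))[[2]]
}

#' Petrosian fractal dimension
#'
#' Sign-change estimator: with `n` samples and `n_delta` sign changes in the
#' first difference, the dimension is
#' `log10(n) / (log10(n) + log10(n / (n + 0.4 * n_delta)))`. A constant series
#' has no sign changes and returns exactly 1.
#'
#' @param x numeric series of length at least 2.
#' @return The estimated dimension.
#' @export
petrosian_fd <- function(x) {
  n <- length(x)
  stopifnot(n >= 2)
  s <- sign(diff(x))
  s <- s[s != 0]
  n_delta <- if (length(s) < 2) 0L else sum(diff(s) != 0)
  log10(n) / (log10(n) + log10(n / (n + 0.4 * n_delta)))
}

#' Hurst exponent by rescaled-range analysis
#'
#' Classic R/S estimation over dyadic window sizes (8, 16, 32, ... up to half
#' the series length): each window's range of cumulative mean-deviations is
#' rescaled by its standard deviation, block-averaged per size, and the
#' exponent is the slope of log(R/S) against log(size). Uncorrelated noise has
#' H near 0.5. Degenerate inputs (constant series, fewer than two usable
#' sizes) return the sentinel 0.5.
#'
#' @param x numeric series of length at least 32.
#' @param min_window smallest window size (default 8).
#' @return The estimated exponent (typically in \eqn{[0, 1]}).
#' @export
hurst_rs <- function(x, min_window = 8L) {
  n <- length(x)
  stopifnot(n >= 32)
  sizes <- min_window * 2^(0:floor(log2(n / min_window / 2)))
  sizes <- sizes[sizes <= n %/% 2]
  if (length(sizes) < 2) return(0.5)
  rs_mean <- vapply(sizes, function(w) {
    n_blocks <- n %/% w
    rs <- vapply(seq_len(n_blocks), function(b) {
      seg <- x[((b - 1) * w + 1):(b * w)]
      s <- sd(seg)
      if (!is.finite(s) || s < 1e-12) return(NA_real_)
      z <- cumsum(seg - mean(seg))
      (max(z) - min(z)) / s
    }, numeric(1))
    mean(rs, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs_mean) & rs_mean > 0
  if (sum(ok) < 2) return(0.5)
  stats::coef(stats::lm(log(rs_mean[ok]) ~ log(sizes[ok])))[[2]]
}

#' The three complexity estimators of one series
#'
#' Applies [higuchi_fd()], [petrosian_fd()] and [hurst_rs()] to a series and
#' guarantees finite results: a constant series yields the sentinels
#' Higuchi = 1, Petrosian = 1, Hurst = 0.5.
#'
#' @param x numeric series of length at least 32.
#' @param k_max Higuchi scale limit.
#' @return Named numeric vector `c(higuchi, petrosian, hurst)`.
#' @export
fractal_trio <- function(x, k_max = 8L) {
  n <- length(x)
  if (n < 32) abort("series must have at least 32 values")
  if (any(!is.finite(x))) abort("series contains non-finite values")
  out <- c(higuchi = higuchi_fd(x, k_max),
           petrosian = petrosian_fd(x),
           hurst = hurst_rs(x))
  stopifnot(all(is.finite(out)))
  out
}
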