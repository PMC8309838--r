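# Local ternary patterns over a temperature grid.
#
# Each interior pixel's 8-neighbourhood is coded ternary against a dead-zone
# threshold t (degrees Celsius): +1 where the neighbour exceeds center + t,
# -1 where it is below center - t, 0 otherwise. "Spectrum k" collects the
# pixels whose neighbourhood contains exactly k codes of +1, so the nine
# spectra (k = 0..8) partition the interior pixels.

# Neighbour offsets, fixed clockwise order starting at the top-left.
LTP_OFFSETS <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, 1L),
                    c(1L, 1L), c(1L, 0L), c(1L, -1L), c(0L, -1L))

# Counts of +1 / -1 codes and packed binary code maps over interior pixels.
ltp_code_maps <- function(roi, t = 0.1) {
  stopifnot(inherits(roi, "roi_matrix"), t > 0)
  v <- roi$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 3 || nc < 3) abort("ROI must be at least 3x3 for local ternary patterns")
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  center <- v[ri, ci, drop = FALSE]
  upper_n <- matrix(0L, nr - 2L, nc - 2L)
  lower_n <- matrix(0L, nr - 2L, nc - 2L)
  upper_code <- matrix(0L, nr - 2L, nc - 2L)
  lower_code <- matrix(0L, nr - 2L, nc - 2L)
  for (k in seq_along(LTP_OFFSETS)) {
    off <- LTP_OFFSETS[[k]]
    nb <- v[ri + off[1], ci + off[2], drop = FALSE]
    up <- nb > center + t
    lo <- nb < center - t
    upper_n <- upper_n + up
    lower_n <- lower_n + lo
    bit <- 2L^(k - 1L)
    upper_code <- upper_code + bit * up
    lower_code <- lower_code + bit * lo
  }
  interior_mask <- roi$mask[ri, ci, drop = FALSE] == 1
  list(upper_n = upper_n, lower_n = lower_n,
       upper_code = upper_code, lower_code = lower_code,
       interior_mask = interior_mask)
}

#' Local ternary pattern spectrum maps
#'
#' Returns the nine binary spectrum maps of a ROI: map `k` marks interior
#' pixels whose 8-neighbourhood contains exactly `k` codes of +1 under the
#' dead-zone threshold `t`. The maps partition the interior pixels (each
#' pixel belongs to exactly one spectrum); pixels outside the tissue mask are
#' zeroed in every map.
#'
#' @param roi a [roi_matrix()] of at least 3x3.
#' @param t dead-zone threshold in degrees Celsius (default 0.1, a typical
#'   thermal-camera sensitivity).
#' @return List with `maps` (list of nine 0/1 matrices over the interior
#'   grid, named `s0`..`s8`), `interior_mask`, and `n_interior` (count of
#'   masked-in interior pixels).
#' @export
ltp_spectrum_maps <- function(roi, t = 0.1) {
  cm <- ltp_code_maps(roi, t)
  maps <- lapply(0:8, function(k) {
    m <- (cm$upper_n == k) & cm$interior_mask
    storage.mode(m) <- "integer"
    m
  })
  names(maps) <- paste0("s", 0:8)
  list(maps = maps, interior_mask = cm$interior_mask,
       n_interior = sum(cm$interior_mask))
}

# Normalized 25-bin histograms of the packed upper- and lower-polarity LTP
# codes over masked interior pixels (50 values per breast).
ltp_histogram_features <- function(roi, t = 0.1, bins = 25L) {
  cm <- ltp_code_maps(roi, t)
  inside <- cm$interior_mask
  if (!any(inside)) abort("empty ROI interior")
  breaks <- seq(0, 256, length.out = bins + 1L)
  h <- function(codes) {
    counts <- tabulate(findInterval(codes[inside], breaks,
                                    rightmost.closed = TRUE), nbins = bins)
    counts / sum(counts)
  }
  out <- c(h(cm$upper_code), h(cm$lower_code))
  names(out) <- c(sprintf("ltph_upper_b%02d", seq_len(bins)),
                  sprintf("ltph_lower_b%02d", seq_len(bins)))
  out
}

# Crop a spectrum map to the bounding box of the masked-in interior pixels.
crop_to_mask_bbox <- function(map, interior_mask) {
  rows <- which(rowSums(interior_mask) > 0)
  cols <- which(colSums(interior_mask) > 0)
  map[min(rows):max(rows), min(cols):max(cols), drop = FALSE]
}
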