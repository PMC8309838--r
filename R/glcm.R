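# Gray-level co-occurrence features over a masked temperature grid.
#
# Temperatures inside the mask are min-max quantized per breast to 256 gray
# levels, removing absolute-temperature offsets between patients. Pairs are
# counted at distance 1 in the four standard directions; only pairs with both
# pixels inside the mask contribute. The matrix is symmetrized and normalized
# before descriptors are taken.

GLCM_DESCRIPTORS <- c("contrast", "dissimilarity", "homogeneity", "energy",
                      "correlation", "asm")
GLCM_ANGLES <- c(0, 45, 90, 135)
# row/col offsets per angle (rows grow downward, 45 degrees = up-right)
GLCM_OFFSETS <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                     `90` = c(-1L, 0L), `135` = c(-1L, -1L))

quantize_roi <- function(roi, levels = 256L) {
  v <- roi$values
  inside <- roi$mask == 1
  if (!any(inside)) abort("empty ROI")
  rng <- range(v[inside])
  q <- matrix(0L, nrow(v), ncol(v))
  if (diff(rng) > 0) {
    scaled <- (v - rng[1]) / diff(rng)
    q[inside] <- pmin(as.integer(floor(scaled[inside] * levels)), levels - 1L)
  }
  q
}

# Sparse symmetric normalized co-occurrence distribution for one offset:
# returns (i, j, p) triplets with 0-based levels.
glcm_pairs <- function(q, mask, offset, levels = 256L) {
  nr <- nrow(q); nc <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  r0 <- max(1L, 1L - dr):min(nr, nr - dr)
  c0 <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- q[r0, c0, drop = FALSE]
  b <- q[r0 + dr, c0 + dc, drop = FALSE]
  ok <- (mask[r0, c0, drop = FALSE] == 1) & (mask[r0 + dr, c0 + dc, drop = FALSE] == 1)
  i <- a[ok]; j <- b[ok]
  if (length(i) == 0) {
    return(list(i = integer(0), j = integer(0), p = numeric(0), n_pairs = 0L))
  }
  # symmetrize by counting both orientations of every pair
  key <- c(i * levels + j, j * levels + i)
  cnt <- table(key)
  keys <- as.numeric(names(cnt))
  list(i = floor(keys / levels), j = keys %% levels,
       p = as.numeric(cnt) / sum(cnt), n_pairs = length(i))
}

glcm_descriptors_sparse <- function(i, j, p) {
  if (length(p) == 0) {
    return(stats::setNames(rep(NA_real_, length(GLCM_DESCRIPTORS)), GLCM_DESCRIPTORS))
  }
  dif <- i - j
  contrast <- sum(p * dif^2)
  dissim <- sum(p * abs(dif))
  homog <- sum(p / (1 + dif^2))
  asm <- sum(p^2)
  energy <- sqrt(asm)
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  var_i <- sum(p * (i - mu_i)^2); var_j <- sum(p * (j - mu_j)^2)
  correlation <- if (var_i < 1e-300 || var_j < 1e-300) 0 else
    sum(p * (i - mu_i) * (j - mu_j)) / sqrt(var_i * var_j)
  c(contrast = contrast, dissimilarity = dissim, homogeneity = homog,
    energy = energy, correlation = correlation, asm = asm)
}

#' Co-occurrence texture features of one breast ROI
#'
#' Computes the six standard descriptors (contrast, dissimilarity,
#' homogeneity, energy, correlation, angular second moment) of the symmetric
#' normalized gray-level co-occurrence matrix at distance 1 in the four
#' standard directions (0, 45, 90, 135 degrees), over 256 quantized
#' temperature levels. Only pixel pairs lying entirely inside the mask are
#' counted. For a constant ROI (a single gray level) contrast is 0, energy 1
#' and correlation is defined as 0.
#'
#' @param roi a [roi_matrix()].
#' @param levels number of quantization levels (default 256).
#' @return Named numeric vector of 24 values in descriptor-major order
#'   (`glcm_contrast_a0`, `glcm_contrast_a45`, ..., `glcm_asm_a135`).
#' @export
glcm_features <- function(roi, levels = 256L) {
  stopifnot(inherits(roi, "roi_matrix"))
  if (sum(roi$mask) == 0) abort("empty ROI")
  q <- quantize_roi(roi, levels)
  per_angle <- lapply(GLCM_OFFSETS, function(off) {
    pr <- glcm_pairs(q, roi$mask, off, levels)
    if (pr$n_pairs == 0) abort("no co-occurring masked pixel pairs in some direction")
    glcm_descriptors_sparse(pr$i, pr$j, pr$p)
  })
  out <- numeric(0)
  for (dsc in GLCM_DESCRIPTORS) {
    for (ang in as.character(GLCM_ANGLES)) {
      out <- c(out, stats::setNames(per_angle[[ang]][[dsc]],
                                    sprintf("glcm_%s_a%s", dsc, ang)))
    }
  }
  out
}
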