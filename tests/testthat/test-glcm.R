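# Brute-force co-occurrence oracle: loops over every pixel pair at the given
# offset, counts both orientations, normalizes, and computes descriptors from
# the dense matrix. Independent of the package's sparse shifted-matrix path.
brute_glcm <- function(q, mask, offset, levels = 256) {
  counts <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + offset[1]; c2 <- c + offset[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (mask[r, c] == 0 || mask[r2, c2] == 0) next
      i <- q[r, c] + 1; j <- q[r2, c2] + 1
      counts[i, j] <- counts[i, j] + 1
      counts[j, i] <- counts[j, i] + 1
    }
  }
  p <- counts / sum(counts)
  iv <- matrix(0:(levels - 1), levels, levels)
  jv <- t(iv)
  mu_i <- sum(p * iv); mu_j <- sum(p * jv)
  s_i <- sqrt(sum(p * (iv - mu_i)^2)); s_j <- sqrt(sum(p * (jv - mu_j)^2))
  list(
    p = p,
    contrast = sum(p * (iv - jv)^2),
    dissimilarity = sum(p * abs(iv - jv)),
    homogeneity = sum(p / (1 + (iv - jv)^2)),
    asm = sum(p^2),
    energy = sqrt(sum(p^2)),
    correlation = if (s_i == 0 || s_j == 0) 0 else
      sum(p * (iv - mu_i) * (jv - mu_j)) / (s_i * s_j)
  )
}

test_that("a constant ROI has zero contrast, unit energy and zero correlation", {
  v <- glcm_features(const_roi(8))
  for (a in c(0, 45, 90, 135)) {
    expect_equal(v[[sprintf("glcm_contrast_a%d", a)]], 0)
    expect_equal(v[[sprintf("glcm_energy_a%d", a)]], 1)
    expect_equal(v[[sprintf("glcm_correlation_a%d", a)]], 0)
  }
})

test_that("descriptors match the brute-force pair-counting oracle", {
  # horizontal stripes of two temperatures quantize to levels 0 and 255
  stripes <- roi_matrix(matrix(rep(c(30, 31), each = 4), 4, 4, byrow = TRUE),
                        side = "left")
  got <- glcm_features(stripes)
  q <- matrix(rep(c(0L, 255L), each = 4), 4, 4, byrow = TRUE)
  offsets <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
                  `135` = c(-1, -1))
  for (a in names(offsets)) {
    want <- brute_glcm(q, matrix(1, 4, 4), offsets[[a]])
    for (d in c("contrast", "dissimilarity", "homogeneity", "energy",
                "correlation", "asm")) {
      expect_equal(got[[sprintf("glcm_%s_a%s", d, a)]], want[[d]],
                   tolerance = 1e-12,
                   label = sprintf("%s at %s degrees", d, a))
    }
  }
  # direction 0: all horizontal neighbours are equal-level pairs
  expect_equal(got[["glcm_contrast_a0"]], 0)
  # direction 90: every vertical pair straddles the stripes
  expect_gt(got[["glcm_contrast_a90"]], 0)

  # irregular masked ROI against the same oracle
  set.seed(7)
  vals <- matrix(runif(64, 30, 34), 8, 8)
  mask <- matrix(rbinom(64, 1, 0.8), 8, 8)
  mask[1:3, 1:6] <- 1  # guarantee enough masked cells
  roi <- roi_matrix(vals, mask, side = "right")
  got <- glcm_features(roi)
  rng <- range(vals[mask == 1])
  q <- matrix(0L, 8, 8)
  inside <- mask == 1
  q[inside] <- pmin(as.integer(floor((vals[inside] - rng[1]) / diff(rng) * 256)), 255L)
  for (a in names(offsets)) {
    want <- brute_glcm(q, mask, offsets[[a]])
    expect_equal(got[[sprintf("glcm_contrast_a%s", a)]], want$contrast,
                 tolerance = 1e-12)
    expect_equal(got[[sprintf("glcm_correlation_a%s", a)]], want$correlation,
                 tolerance = 1e-12)
  }
})

test_that("output has 24 deterministically ordered values", {
  roi <- noise_roi(12, seed = 3)
  v1 <- glcm_features(roi)
  v2 <- glcm_features(roi)
  expect_length(v1, 24)
  expect_identical(v1, v2)
  expect_identical(names(v1)[1:4],
                   c("glcm_contrast_a0", "glcm_contrast_a45",
                     "glcm_contrast_a90", "glcm_contrast_a135"))
  expect_false(anyDuplicated(names(v1)) > 0)
})

test_that("invalid ROIs are rejected", {
  expect_error(roi_matrix(matrix(1, 3, 3)), "at least 16")
  vals <- matrix(33, 5, 5); vals[2, 2] <- NA
  expect_error(roi_matrix(vals), "non-finite")
  # non-finite outside the mask is tolerated
  mask <- matrix(1, 5, 5); mask[2, 2] <- 0
  expect_silent(roi_matrix(vals, mask))
})
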