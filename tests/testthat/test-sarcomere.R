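# Line profiles, spectral sarcomere-length estimation, orientation
# histograms and the alignment index.

test_that("line_profile validates sample count and uniform spacing", {
  expect_error(line_profile(seq(0, 1, length.out = 10), rnorm(10)),
               class = "cmquant_invalid_profile")
  pos <- c(seq(0, 3, by = 0.1), 3.25)
  expect_error(line_profile(pos, rnorm(length(pos))),
               class = "cmquant_invalid_profile")
})

test_that("a horizontal scan across vertical stripes recovers the stripe period", {
  g <- gen_striated_image(striated_image_spec(spacing = 1.8,
                                              pixel_size = 0.1,
                                              shape = c(128L, 256L),
                                              seed = 1L))
  prof <- extract_line_profile(g$image, c(64, 2), c(64, 253), width_px = 5L,
                               pixel_size = 0.1)
  est <- estimate_sarcomere_length(prof)
  expect_identical(est$status, "ok")
  expect_lt(abs(est$length - 1.8) / 1.8, 0.02)
})

test_that("wider perpendicular averaging reduces profile noise variance", {
  g <- gen_striated_image(striated_image_spec(spacing = 2, snr = 2,
                                              shape = c(128L, 256L),
                                              seed = 8L))
  p1 <- extract_line_profile(g$image, c(64, 2), c(64, 253), width_px = 1L,
                             pixel_size = 0.1)
  p9 <- extract_line_profile(g$image, c(64, 2), c(64, 253), width_px = 9L,
                             pixel_size = 0.1)
  # compare high-frequency (noise-dominated) residual after smoothing
  resid_var <- function(p) {
    sm <- stats::filter(p$intensities, rep(1 / 5, 5), sides = 2)
    stats::var(p$intensities - sm, na.rm = TRUE)
  }
  expect_lt(resid_var(p9), resid_var(p1))
})

test_that("a scan parallel to the bands is reported undetermined", {
  g <- gen_striated_image(striated_image_spec(spacing = 2, pixel_size = 0.1,
                                              shape = c(128L, 256L),
                                              seed = 1L))
  col <- 128  # along a stripe: constant intensity down the column
  prof <- extract_line_profile(g$image, c(2, col), c(125, col),
                               width_px = 1L, pixel_size = 0.1)
  est <- estimate_sarcomere_length(prof)
  expect_identical(est$status, "undetermined")
  expect_true(is.na(est$length))
})

test_that("ROI validation rejects bad endpoints and widths", {
  img <- matrix(runif(64 * 64), 64, 64)
  expect_error(extract_line_profile(img, c(0, 0), c(0, 100), 1L, 0.1),
               class = "cmquant_invalid_roi")
  expect_error(extract_line_profile(img, c(5, 5), c(5, 5), 1L, 0.1),
               class = "cmquant_invalid_roi")
  expect_error(extract_line_profile(img, c(0, 0), c(0, 63), 2L, 0.1),
               class = "cmquant_invalid_roi")
})

test_that("noise-free sinusoid of period 2.0 um is recovered within 0.04 um", {
  x <- seq(0, by = 0.1, length.out = 256)
  prof <- line_profile(x, 0.5 + 0.5 * cos(2 * pi * x / 2))
  est <- estimate_sarcomere_length(prof)
  expect_identical(est$status, "ok")
  expect_lt(abs(est$length - 2), 0.04)
})

test_that("constant profile is undetermined, never a silent number", {
  x <- seq(0, by = 0.1, length.out = 128)
  est <- estimate_sarcomere_length(line_profile(x, rep(3, 128)))
  expect_identical(est$status, "undetermined")
  expect_true(is.na(est$length))
})

test_that("peak-spacing method agrees with the spectral method", {
  x <- seq(0, by = 0.1, length.out = 256)
  y <- 0.5 + 0.5 * cos(2 * pi * x / 1.9)
  sp <- estimate_sarcomere_length(line_profile(x, y), method = "spectral")
  pk <- estimate_sarcomere_length(line_profile(x, y),
                                  method = "peak-spacing")
  expect_identical(pk$status, "ok")
  expect_lt(abs(pk$length - sp$length), 0.05)
})

test_that("spectral estimator matches the dense-spectrum oracle", {
  set.seed(314)
  for (i in 1:20) {
    spacing <- runif(1, 1.6, 2.3)
    x <- seq(0, by = 0.1, length.out = 256)
    y <- 0.5 + 0.5 * cos(2 * pi * x / spacing + runif(1, 0, 2 * pi)) +
      rnorm(256, 0, 0.1)
    est <- estimate_sarcomere_length(line_profile(x, y))
    expect_identical(est$status, "ok")
    oracle <- dense_spectrum_length(y, 0.1)
    # agreement within one refined bin of the estimator's padded grid
    nfft <- 2^ceiling(log2(256)) * 8
    expect_lt(abs(1 / est$length - 1 / oracle), 1 / (nfft * 0.1))
  }
})

test_that("orientation histogram of transverse bands peaks at +/-90 degrees", {
  g <- gen_striated_image(striated_image_spec(spacing = 2, seed = 1L))
  h <- orientation_histogram(g$image)
  shoulders <- abs(h$bin_centers) >= 70
  expect_gt(sum(h$weights[shoulders]) / sum(h$weights), 0.8)
})

test_that("histogram is rotation-equivariant when the reference axis follows", {
  base <- gen_striated_image(striated_image_spec(spacing = 2,
                                                 orientation_deg = 0,
                                                 dispersion_deg = 10,
                                                 seed = 6L))
  rot <- gen_striated_image(striated_image_spec(spacing = 2,
                                                orientation_deg = 30,
                                                dispersion_deg = 10,
                                                seed = 6L))
  i0 <- alignment_index(orientation_histogram(base$image,
                                              reference_axis_deg = 0))$index
  i30 <- alignment_index(orientation_histogram(rot$image,
                                               reference_axis_deg = 30))$index
  # pixel-grid discretization of the rotated bands perturbs the index by
  # roughly 10% at dispersion 10 degrees
  expect_lt(abs(i0 - i30) / i0, 0.15)
})

test_that("isotropic texture gives a near-uniform histogram and index near 1", {
  set.seed(21)
  img <- matrix(rnorm(128 * 128), 128, 128)
  h <- orientation_histogram(img, bin_width_deg = 15)
  ai <- alignment_index(h)
  expect_lt(abs(ai$index - 1), 0.2)
  # chi-square GOF with an effective sample size of one observation per
  # non-overlapping tensor-smoothing window (weights are spatially
  # correlated, so raw pixel counts would overstate the evidence)
  interior <- 128 - 2 * (ceiling(2 * 2) + 2)
  n_eff <- floor(interior^2 / (4 * 2 + 1)^2)
  counts <- h$weights / sum(h$weights) * n_eff
  expected <- n_eff / length(counts)
  x2 <- sum((counts - expected)^2 / expected)
  expect_lt(x2, qchisq(0.99, df = length(counts) - 1))
})

test_that("zero-gradient image raises a zero-weight error", {
  expect_error(orientation_histogram(matrix(1, 64, 64)),
               class = "cmquant_zero_weight")
  expect_error(orientation_histogram(matrix(1, 10, 10)),
               class = "cmquant_invalid_image")
  expect_error(orientation_histogram(matrix(runif(64^2), 64, 64),
                                     bin_width_deg = 7),
               class = "cmquant_invalid_spec")
})

test_that("alignment index closed forms hold exactly", {
  centers <- seq(-89.5, 90, by = 1)
  uni <- alignment_index(orientation_histogram_from_weights(
    centers, rep(1, 180)))
  expect_lt(abs(uni$index - 1), 1e-9)
  expect_equal(uni$eta_ir / (uni$eta_ir + uni$omega_ir), 2 / 9)

  all90 <- rep(0, 180); all90[180] <- 1   # bin centred at 89.5
  expect_equal(alignment_index(orientation_histogram_from_weights(
    centers, all90))$index, 4.5)

  half <- rep(0, 180); half[180] <- 1; half[91] <- 1  # 89.5 and 0.5 degrees
  expect_equal(alignment_index(orientation_histogram_from_weights(
    centers, half))$index, 2.25)
})

test_that("alignment index is invariant to weight rescaling and bin phase", {
  centers <- seq(-89.5, 90, by = 1)
  w <- runif(180) + 0.1
  a <- alignment_index(orientation_histogram_from_weights(centers, w))
  b <- alignment_index(orientation_histogram_from_weights(centers, 7.3 * w))
  expect_equal(a$index, b$index)
  expect_equal(a$eta + a$omega, sum(w))
  # boundary bins split proportionally: a 15-degree window cuts the
  # 1-degree bins cleanly, a 15.5-degree window splits two bins in half;
  # under a uniform histogram both must give exactly index 1
  u <- orientation_histogram_from_weights(centers, rep(1, 180))
  expect_equal(alignment_index(u, window_deg = 15.5)$index, 1)
})
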