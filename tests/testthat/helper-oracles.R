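# Independent oracle implementations used only by the tests.

# Brute-force dense-spectrum sarcomere-length oracle: argmax of the
# periodogram over a heavily zero-padded grid (no parabolic refinement).
# Intentionally shares no code with estimate_sarcomere_length().
dense_spectrum_length <- function(intensities, pixel_size,
                                  search_band = c(1.4, 3.0),
                                  pad_factor = 64) {
  y <- intensities - mean(intensities)
  n <- length(y)
  # same detrend + window family as any periodogram approach
  tt <- seq_len(n)
  y <- stats::lm(y ~ tt)$residuals
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  y <- y * w
  nfft <- 2^ceiling(log2(n * pad_factor))
  p <- Mod(stats::fft(c(y, rep(0, nfft - n))))^2
  freqs <- (seq_len(nfft) - 1) / (nfft * pixel_size)
  keep <- freqs > 0 & freqs >= 1 / search_band[2] & freqs <= 1 / search_band[1]
  1 / freqs[keep][which.max(p[keep])]
}

# Rasterize an ellipse with semi-axes (a, b) pixels, axis-aligned, into an
# integer mask on an n x n canvas.
raster_ellipse <- function(a, b, n, label = 1L) {
  m <- matrix(0L, n, n)
  cx <- n / 2   # integer centre: matches the frozen oracle rasterization
  for (r in seq_len(n)) for (c in seq_len(n)) {
    if (((c - cx) / a)^2 + ((r - cx) / b)^2 <= 1) m[r, c] <- label
  }
  m
}

raster_disk <- function(radius, n, label = 1L) {
  raster_ellipse(radius, radius, n, label)
}

# 95% binomial (normal-approximation) confidence half-width check.
within_binomial_ci <- function(estimate, p_true, n) {
  half <- 1.96 * sqrt(p_true * (1 - p_true) / n)
  abs(estimate - p_true) <= half
}
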