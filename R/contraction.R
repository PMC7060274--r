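# Per-frame sarcomere length from paced contraction time-lapses and percent
# sarcomere shortening.

#' Per-frame sarcomere length from a contraction time-lapse
#'
#' Applies the spectral sarcomere-length estimator to the same line-scan
#' region of every frame. Frames whose spectral peak does not reach the
#' confidence threshold are marked missing, never interpolated; a trace with
#' more than `max_undetermined` missing frames is rejected.
#'
#' @param stack numeric array `(time, rows, cols)` (a 2D matrix is treated
#'   as a single frame).
#' @param times frame times in seconds (uniform), same length as the stack's
#'   first dimension.
#' @param pacing_hz pacing frequency in Hz, from the acquisition protocol.
#' @param pixel_size micrometres per pixel.
#' @param roi list with `start`, `end` (0-based `c(row, col)`) and
#'   `width_px`; defaults to a horizontal line through the middle row.
#' @param max_undetermined maximum tolerated fraction of undetermined
#'   frames (default 0.2).
#' @param ... passed to [estimate_sarcomere_length()].
#' @return An object of class `contraction_trace`: data.frame-like list with
#'   `times`, `lengths` (um, `NA` where undetermined), `pacing_hz`, `roi`.
#' @export
framewise_sarcomere_length <- function(stack, times, pacing_hz, pixel_size,
                                       roi = NULL, max_undetermined = 0.2,
                                       ...) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(1L, dim(stack)))
  stopifnot(length(dim(stack)) == 3L)
  nt <- dim(stack)[1]
  if (nt < 2L) abort_cmq("need at least 2 frames", "cmquant_invalid_stack")
  stopifnot(length(times) == nt)
  nr <- dim(stack)[2]; nc <- dim(stack)[3]
  if (is.null(roi)) {
    mid <- floor(nr / 2)
    roi <- list(start = c(mid, 1), end = c(mid, nc - 2), width_px = 5L)
  }
  lengths <- vapply(seq_len(nt), function(i) {
    prof <- extract_line_profile(stack[i, , ], roi$start, roi$end,
                                 width_px = roi$width_px,
                                 pixel_size = pixel_size)
    est <- estimate_sarcomere_length(prof, method = "spectral", ...)
    if (est$status == "ok") est$length else NA_real_
  }, numeric(1))
  frac_na <- mean(is.na(lengths))
  if (frac_na > max_undetermined) {
    abort_cmq(sprintf(
      "trace rejected: %.0f%% of frames undetermined (limit %.0f%%)",
      100 * frac_na, 100 * max_undetermined), "cmquant_trace_rejected")
  }
  structure(list(times = times, lengths = lengths, pacing_hz = pacing_hz,
                 roi = roi), class = "contraction_trace")
}

#' Construct a contraction trace from precomputed lengths
#'
#' @param times frame times in seconds, strictly increasing and uniform.
#' @param lengths per-frame sarcomere lengths in micrometres (`NA` where
#'   undetermined).
#' @param pacing_hz pacing frequency in Hz.
#' @return A `contraction_trace`.
#' @export
contraction_trace <- function(times, lengths, pacing_hz) {
  stopifnot(length(times) == length(lengths))
  d <- diff(times)
  if (any(d <= 0) || (max(d) - min(d)) > 1e-9 * mean(d)) {
    abort_cmq("times must be strictly increasing and uniform",
              "cmquant_invalid_trace")
  }
  if (any(lengths <= 0, na.rm = TRUE)) {
    abort_cmq("determined lengths must be positive", "cmquant_invalid_trace")
  }
  structure(list(times = times, lengths = lengths, pacing_hz = pacing_hz,
                 roi = NULL), class = "contraction_trace")
}

#' Percent sarcomere shortening from a paced length trace
#'
#' Beats are segmented by the known pacing period (cycles anchored at the
#' trace start). The diastolic (resting) length is the 95th percentile of
#' determined lengths — robust to single-frame spectral outliers — and the
#' systolic length is the mean of per-beat minima; percent shortening is
#' `(resting - systolic) / resting * 100`.
#'
#' @param trace a `contraction_trace`.
#' @return An object of class `shortening_metrics` with `resting_length`,
#'   `min_length`, `percent_shortening`, `normalized_trace`, `per_beat_min`
#'   and `n_beats`.
#' @export
shortening_metrics <- function(trace) {
  stopifnot(inherits(trace, "contraction_trace"))
  period <- 1 / trace$pacing_hz
  t_rel <- trace$times - trace$times[1]
  dt <- t_rel[2] - t_rel[1]
  n_beats <- as.integer(floor((t_rel[length(t_rel)] + dt + 1e-9) / period))
  if (n_beats < 2L) {
    abort_cmq("fewer than 2 complete pacing cycles in the trace: no beats to segment",
              "cmquant_no_beats")
  }
  beat_id <- floor(t_rel / period + 1e-9)
  in_complete <- beat_id < n_beats
  per_beat_min <- vapply(seq_len(n_beats) - 1L, function(b) {
    v <- trace$lengths[in_complete & beat_id == b]
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(per_beat_min))) {
    abort_cmq("no determined lengths in any beat", "cmquant_no_beats")
  }
  resting <- stats::quantile(trace$lengths, 0.95, na.rm = TRUE, names = FALSE)
  min_len <- mean(per_beat_min, na.rm = TRUE)
  structure(list(resting_length = resting, min_length = min_len,
                 percent_shortening = (resting - min_len) / resting * 100,
                 normalized_trace = trace$lengths / resting,
                 per_beat_min = per_beat_min,
                 n_beats = n_beats),
            class = "shortening_metrics")
}
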