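# Control-quantile fluorescence gating of event intensity tables.

#' Gate a fluorescence sample against a negative control
#'
#' The threshold is the `control_quantile` quantile (type 1, inverted ECDF,
#' hence exactly rank-based) of the control intensities; events strictly
#' above it are positive. Intensity summaries (mean and median) are
#' computed only over gated events. An empty gated set yields fraction 0
#' with the intensity summary flagged undefined, not an exception.
#'
#' @param sample data.frame with an `intensity` column (the measured
#'   sample); rows with a `viable` column equal to `FALSE` are dropped
#'   first (dead-cell pre-filter).
#' @param control data.frame with an `intensity` column (negative/unstained
#'   control).
#' @param control_quantile control quantile defining the gate (default
#'   0.999).
#' @return An object of class `gate_result` with `threshold`,
#'   `fraction_positive`, `positive_mean`, `positive_median`, `n_events`,
#'   `n_positive` and `intensity_defined`.
#' @export
gate_positive <- function(sample, control, control_quantile = 0.999) {
  check_scalar(control_quantile, "control_quantile", lower = 0, upper = 1)
  for (nm in c("sample", "control")) {
    tab <- get(nm)
    if (!is.data.frame(tab) || !"intensity" %in% names(tab) ||
        nrow(tab) == 0L) {
      abort_cmq(sprintf("`%s` must be a non-empty data.frame with an `intensity` column",
                        nm), "cmquant_invalid_events")
    }
    if (any(!is.finite(tab$intensity))) {
      abort_cmq(sprintf("`%s` intensities must be finite", nm),
                "cmquant_invalid_events")
    }
  }
  if ("viable" %in% names(sample)) sample <- sample[sample$viable, ,
                                                   drop = FALSE]
  thr <- stats::quantile(control$intensity, control_quantile, type = 1,
                         names = FALSE)
  pos <- sample$intensity > thr
  n_pos <- sum(pos)
  structure(list(threshold = thr,
                 fraction_positive = n_pos / nrow(sample),
                 positive_mean = if (n_pos > 0L)
                   mean(sample$intensity[pos]) else NA_real_,
                 positive_median = if (n_pos > 0L)
                   stats::median(sample$intensity[pos]) else NA_real_,
                 n_events = nrow(sample), n_positive = n_pos,
                 intensity_defined = n_pos > 0L),
            class = "gate_result")
}
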