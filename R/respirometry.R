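# Mitochondrial stress-test OCR partitioning: basal, ATP-linked, proton
# leak and maximal respiration from a four-phase injection series.

#' Construct an OCR series
#'
#' @param times measurement times in minutes, increasing.
#' @param ocr oxygen consumption rates, pmol O2/min.
#' @param injections data.frame with columns `event` (in order
#'   `oligomycin`, `FCCP`, `rotenone_antimycin`) and `time` (minutes).
#' @param well_id,group optional labels carried through summaries.
#' @return An object of class `ocr_series`.
#' @export
ocr_series <- function(times, ocr, injections, well_id = "well1",
                       group = "group1") {
  stopifnot(length(times) == length(ocr), !is.unsorted(times))
  expected <- c("oligomycin", "FCCP", "rotenone_antimycin")
  if (!identical(as.character(injections$event), expected)) {
    abort_cmq("injections must be oligomycin, FCCP, rotenone_antimycin in that order",
              "cmquant_invalid_injections")
  }
  if (is.unsorted(injections$time, strictly = TRUE)) {
    abort_cmq("injection times must be strictly increasing",
              "cmquant_invalid_injections")
  }
  structure(list(times = times, ocr = ocr, injections = injections,
                 well_id = well_id, group = group), class = "ocr_series")
}

#' Partition an OCR series into respiration components
#'
#' Phases are delimited by the injection timestamps. With the default phase
#' statistic (mean of all in-phase measurements):
#' basal = pre-oligomycin mean; ATP-linked = basal minus the post-oligomycin
#' mean (the oligomycin-sensitive rate); proton leak = post-oligomycin mean
#' minus the post-rotenone/antimycin mean; maximal = the post-FCCP mean,
#' reported without non-mitochondrial subtraction (the raw response to
#' FCCP). A corrected maximal (post-FCCP minus post-rotenone/antimycin) is
#' available via `subtract_nonmito`. Negative derived rates are reported and
#' flagged, never clipped, since they signal poorly responding wells.
#'
#' @param series an [ocr_series()].
#' @param phase_statistic `"mean"` (default) or `"last"` (last measurement
#'   of each phase, the common instrument convention).
#' @param subtract_nonmito subtract the post-rotenone/antimycin rate from
#'   maximal respiration (default FALSE).
#' @return An object of class `respiration_metrics` with `basal`,
#'   `atp_linked`, `proton_leak`, `maximal`, `nonmito`, `phase_means`,
#'   `flagged`, `well_id`, `group`.
#' @export
partition_ocr <- function(series, phase_statistic = c("mean", "last"),
                          subtract_nonmito = FALSE) {
  stopifnot(inherits(series, "ocr_series"))
  phase_statistic <- match.arg(phase_statistic)
  brk <- c(-Inf, series$injections$time, Inf)
  phase <- findInterval(series$times, brk)
  if (!all(1:4 %in% phase)) {
    abort_cmq("every phase needs at least one measurement",
              "cmquant_empty_phase")
  }
  stat <- function(v) if (phase_statistic == "mean") mean(v) else
    v[length(v)]
  pm <- vapply(1:4, function(p) stat(series$ocr[phase == p]), numeric(1))
  names(pm) <- c("baseline", "post_oligomycin", "post_fccp",
                 "post_rotenone_antimycin")
  basal <- pm[["baseline"]]
  atp_linked <- basal - pm[["post_oligomycin"]]
  proton_leak <- pm[["post_oligomycin"]] - pm[["post_rotenone_antimycin"]]
  maximal <- pm[["post_fccp"]] -
    if (subtract_nonmito) pm[["post_rotenone_antimycin"]] else 0
  structure(list(basal = basal, atp_linked = atp_linked,
                 proton_leak = proton_leak, maximal = maximal,
                 nonmito = pm[["post_rotenone_antimycin"]],
                 phase_means = pm,
                 flagged = atp_linked < 0 || proton_leak < 0,
                 well_id = series$well_id, group = series$group),
            class = "respiration_metrics")
}

#' Per-group summary of respiration metrics
#'
#' @param metrics list of `respiration_metrics` (one per well).
#' @return data.frame with per-group, per-metric mean, sd and n. For a
#'   single well, sd is 0 by convention and the row is flagged `n1 = TRUE`.
#' @export
group_summary <- function(metrics) {
  stopifnot(length(metrics) >= 1L,
            all(vapply(metrics, inherits, logical(1),
                       "respiration_metrics")))
  df <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(group = m$group, well_id = m$well_id, basal = m$basal,
               atp_linked = m$atp_linked, proton_leak = m$proton_leak,
               maximal = m$maximal)
  }))
  out <- lapply(split(df, df$group), function(g) {
    do.call(rbind, lapply(c("basal", "atp_linked", "proton_leak",
                            "maximal"), function(metric) {
      v <- g[[metric]]
      data.frame(group = g$group[1], metric = metric, mean = mean(v),
                 sd = if (length(v) > 1L) stats::sd(v) else 0,
                 n = length(v), n1 = length(v) == 1L)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
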