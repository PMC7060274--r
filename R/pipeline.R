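# Reproducible stage runner: config validation, dispatch, atomic outputs
# and a machine-readable run manifest.

# Per-stage config schema: required and optional keys. Every physical
# quantity carries its unit in the key name's documented meaning (um, s,
# Hz, min); unknown keys are rejected outright.
stage_schemas <- function() {
  list(
    generate_striated = list(
      required = c("spacing_um", "pixel_size_um", "seed", "out_dir"),
      optional = c("orientation_deg", "dispersion_deg", "rows", "cols",
                   "snr")),
    generate_calcium = list(
      required = c("seed", "out_dir"),
      optional = c("duration_s", "dt_s", "pacing_hz", "baseline",
                   "amplitude", "rise_time_s", "decay_tau_s", "noise_sd")),
    generate_ocr = list(
      required = c("basal", "atp_linked", "proton_leak", "maximal",
                   "nonmito", "seed", "out_dir"),
      optional = c("n_measurements_per_phase", "noise_sd")),
    generate_cytometry = list(
      required = c("n_events", "positive_fraction", "seed", "out_dir"),
      optional = c("neg_location", "neg_scale", "pos_location",
                   "pos_scale")),
    structure = list(
      required = c("image", "pixel_size_um", "out_dir"),
      optional = c("bin_width_deg", "reference_axis_deg", "window_deg",
                   "line_row", "width_px")),
    calcium = list(
      required = c("trace", "pacing_hz", "out_dir"),
      optional = c("decay_fraction_remaining", "decay_method")),
    respirometry = list(
      required = c("series", "injections", "out_dir"),
      optional = c("phase_statistic", "subtract_nonmito")),
    cytometry = list(
      required = c("sample", "control", "out_dir"),
      optional = c("control_quantile"))
  )
}

#' Validate a stage configuration
#'
#' Checks the stage name, rejects unknown keys, and reports every missing
#' required key by name before any computation runs.
#'
#' @param config named list with a `stage` entry plus stage parameters.
#' @return `config`, invisibly, on success.
#' @export
validate_run_config <- function(config) {
  if (is.null(config$stage)) {
    abort_cmq("config must name a `stage`", "cmquant_config_error")
  }
  schemas <- stage_schemas()
  if (!config$stage %in% names(schemas)) {
    abort_cmq(sprintf("unknown stage `%s` (known: %s)", config$stage,
                      paste(names(schemas), collapse = ", ")),
              "cmquant_config_error")
  }
  sch <- schemas[[config$stage]]
  keys <- setdiff(names(config), "stage")
  unknown <- setdiff(keys, c(sch$required, sch$optional))
  if (length(unknown) > 0L) {
    abort_cmq(sprintf("unknown config key(s) for stage `%s`: %s",
                      config$stage, paste(unknown, collapse = ", ")),
              "cmquant_config_error")
  }
  missing <- setdiff(sch$required, keys)
  if (length(missing) > 0L) {
    abort_cmq(sprintf("stage `%s` is missing required config field(s): %s",
                      config$stage, paste(missing, collapse = ", ")),
              "cmquant_config_error")
  }
  for (f in intersect(c("image", "trace", "series", "injections", "sample",
                        "control"), keys)) {
    if (!file.exists(config[[f]])) {
      abort_cmq(sprintf("input `%s` not found: %s", f, config[[f]]),
                "cmquant_missing_input")
    }
  }
  invisible(config)
}

#' Run one analysis stage from a validated configuration
#'
#' Outputs are written atomically under `config$out_dir`, together with a
#' `manifest.txt` recording the stage, software version, seed, a hash of
#' the configuration and the md5 checksum of every input and output file.
#' Rerunning with an identical config reproduces identical outputs for
#' deterministic stages.
#'
#' @param config named list; see [validate_run_config()].
#' @return Named character vector of output file paths, invisibly.
#' @export
run_stage <- function(config) {
  validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  outputs <- switch(
    config$stage,
    generate_striated = stage_generate_striated(config, out_dir),
    generate_calcium = stage_generate_calcium(config, out_dir),
    generate_ocr = stage_generate_ocr(config, out_dir),
    generate_cytometry = stage_generate_cytometry(config, out_dir),
    structure = stage_structure(config, out_dir),
    calcium = stage_calcium(config, out_dir),
    respirometry = stage_respirometry(config, out_dir),
    cytometry = stage_cytometry(config, out_dir))
  inputs <- unlist(config[intersect(c("image", "trace", "series",
                                      "injections", "sample", "control"),
                                    names(config))])
  write_manifest(config, inputs, outputs, out_dir)
  message(sprintf("[cmquant] stage %s: %d output file(s) in %.2f s",
                  config$stage, length(outputs),
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(outputs)
}

write_manifest <- function(config, inputs, outputs, out_dir) {
  inputs <- as.character(if (is.null(inputs)) character(0) else inputs)
  cfg <- config[order(names(config))]
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file))
  writeLines(vapply(names(cfg), function(k)
    sprintf("%s=%s", k, paste(format(cfg[[k]], digits = 17),
                              collapse = ",")), character(1)), cfg_file)
  md5_entries <- function(paths, prefix) {
    if (length(paths) == 0L) return(list())
    stats::setNames(as.list(unname(tools::md5sum(paths))),
                    vapply(basename(paths), function(b)
                      paste0(prefix, b), character(1)))
  }
  meta <- c(list(stage = config$stage,
                 version = as.character(utils::packageVersion("cmquant")),
                 config_md5 = unname(tools::md5sum(cfg_file)),
                 seed = if (is.null(config$seed)) NA else config$seed),
            md5_entries(inputs, "input_md5_"),
            md5_entries(outputs, "output_md5_"))
  write_sidecar(meta, file.path(out_dir, "manifest.txt"))
}

cfg_get <- function(config, key, default) {
  if (is.null(config[[key]])) default else config[[key]]
}

stage_generate_striated <- function(config, out_dir) {
  spec <- striated_image_spec(
    spacing = config$spacing_um,
    orientation_deg = cfg_get(config, "orientation_deg", 0),
    dispersion_deg = cfg_get(config, "dispersion_deg", 0),
    pixel_size = config$pixel_size_um,
    shape = c(cfg_get(config, "rows", 128L), cfg_get(config, "cols", 128L)),
    snr = cfg_get(config, "snr", Inf), seed = config$seed)
  g <- gen_striated_image(spec)
  img_path <- file.path(out_dir, "striated.tif")
  write_image_stack(g$image, img_path)
  meta_path <- file.path(out_dir, "striated_truth.txt")
  write_sidecar(g$truth, meta_path)
  c(image = img_path, truth = meta_path)
}

stage_generate_calcium <- function(config, out_dir) {
  spec <- trace_spec(
    duration = cfg_get(config, "duration_s", 10),
    dt = cfg_get(config, "dt_s", 0.02),
    pacing_hz = cfg_get(config, "pacing_hz", 1),
    baseline = cfg_get(config, "baseline", 100),
    amplitude = cfg_get(config, "amplitude", 1.5),
    rise_time = cfg_get(config, "rise_time_s", 0.1),
    decay_tau = cfg_get(config, "decay_tau_s", 0.15),
    noise_sd = cfg_get(config, "noise_sd", 0), seed = config$seed)
  g <- gen_calcium_trace(spec)
  tr_path <- file.path(out_dir, "calcium_trace.csv")
  write_table(g$trace, tr_path)
  meta_path <- file.path(out_dir, "calcium_truth.txt")
  write_sidecar(g$truth, meta_path)
  c(trace = tr_path, truth = meta_path)
}

stage_generate_ocr <- function(config, out_dir) {
  spec <- ocr_spec(config$basal, config$atp_linked, config$proton_leak,
                   config$maximal, config$nonmito,
                   n_measurements_per_phase =
                     cfg_get(config, "n_measurements_per_phase", 3L),
                   noise_sd = cfg_get(config, "noise_sd", 0),
                   seed = config$seed)
  g <- gen_ocr_series(spec)
  s_path <- file.path(out_dir, "ocr_series.csv")
  i_path <- file.path(out_dir, "ocr_injections.csv")
  m_path <- file.path(out_dir, "ocr_truth.txt")
  write_table(g$series, s_path)
  write_table(g$injections, i_path)
  write_sidecar(g$truth, m_path)
  c(series = s_path, injections = i_path, truth = m_path)
}

stage_generate_cytometry <- function(config, out_dir) {
  g <- gen_cytometry_sample(
    n_events = config$n_events,
    positive_fraction = config$positive_fraction,
    neg_location = cfg_get(config, "neg_location", 1.5),
    neg_scale = cfg_get(config, "neg_scale", 0.25),
    pos_location = cfg_get(config, "pos_location", 3.0),
    pos_scale = cfg_get(config, "pos_scale", 0.3), seed = config$seed)
  e_path <- file.path(out_dir, "events.csv")
  m_path <- file.path(out_dir, "events_truth.txt")
  write_table(g$events, e_path)
  write_sidecar(g$truth, m_path)
  c(events = e_path, truth = m_path)
}

stage_structure <- function(config, out_dir) {
  img <- read_image_stack(config$image)[1, , ]
  hist <- orientation_histogram(
    img, bin_width_deg = cfg_get(config, "bin_width_deg", 1),
    reference_axis_deg = cfg_get(config, "reference_axis_deg", 0))
  ai <- alignment_index(hist, window_deg = cfg_get(config, "window_deg",
                                                   20))
  mid <- floor(nrow(img) / 2)
  prof <- extract_line_profile(
    img, c(cfg_get(config, "line_row", mid), 2),
    c(cfg_get(config, "line_row", mid), ncol(img) - 3),
    width_px = cfg_get(config, "width_px", 5L),
    pixel_size = config$pixel_size_um)
  est <- estimate_sarcomere_length(prof)
  h_path <- file.path(out_dir, "orientation_histogram.csv")
  r_path <- file.path(out_dir, "structure_metrics.csv")
  write_table(data.frame(bin_center_deg = hist$bin_centers,
                         weight = hist$weights), h_path)
  write_table(data.frame(alignment_index = ai$index, eta = ai$eta,
                         omega = ai$omega,
                         sarcomere_length_um = est$length,
                         length_confidence = est$confidence,
                         length_status = est$status), r_path)
  c(histogram = h_path, metrics = r_path)
}

stage_calcium <- function(config, out_dir) {
  raw <- read_numeric_csv(config$trace, c("time", "intensity"))
  ct <- compute_dff(raw, pacing_hz = config$pacing_hz)
  tm <- transient_metrics(
    ct,
    decay_fraction_remaining = cfg_get(config, "decay_fraction_remaining",
                                       0.1),
    decay_method = cfg_get(config, "decay_method", "expfit"))
  pb_path <- file.path(out_dir, "calcium_per_beat.csv")
  sm_path <- file.path(out_dir, "calcium_summary.csv")
  write_table(tm$per_beat, pb_path)
  write_table(tm$summary, sm_path)
  c(per_beat = pb_path, summary = sm_path)
}

stage_respirometry <- function(config, out_dir) {
  s <- read_numeric_csv(config$series, c("time", "ocr"))
  inj <- read_numeric_csv(config$injections, "time")
  ser <- ocr_series(s$time, s$ocr, inj)
  met <- partition_ocr(
    ser, phase_statistic = cfg_get(config, "phase_statistic", "mean"),
    subtract_nonmito = cfg_get(config, "subtract_nonmito", FALSE))
  m_path <- file.path(out_dir, "respiration_metrics.csv")
  write_table(data.frame(basal = met$basal, atp_linked = met$atp_linked,
                         proton_leak = met$proton_leak,
                         maximal = met$maximal, nonmito = met$nonmito,
                         flagged = met$flagged), m_path)
  c(metrics = m_path)
}

stage_cytometry <- function(config, out_dir) {
  smp <- read_numeric_csv(config$sample, "intensity")
  ctl <- read_numeric_csv(config$control, "intensity")
  g <- gate_positive(smp, ctl,
                     control_quantile = cfg_get(config, "control_quantile",
                                                0.999))
  g_path <- file.path(out_dir, "gate_result.csv")
  write_table(data.frame(threshold = g$threshold,
                         fraction_positive = g$fraction_positive,
                         positive_mean = g$positive_mean,
                         positive_median = g$positive_median,
                         n_events = g$n_events, n_positive = g$n_positive),
              g_path)
  c(gate = g_path)
}
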