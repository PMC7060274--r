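# Seeded generators for every input modality the analysis stages consume.
# Each generator returns the dataset together with a ground-truth record so
# downstream estimators can be tested for parameter recovery.

#' Specification of a synthetic striated (sarcomere-like) image
#'
#' Describes a quasi-periodic banded pattern emulating an alpha-actinin-stained
#' cardiomyocyte: a raised sinusoid along the striation normal, modulated by a
#' smooth cell-shaped envelope, with optional angular dispersion of the local
#' band orientation and additive Gaussian noise.
#'
#' @param spacing sarcomere period in micrometres; must exceed twice the pixel
#'   size (Nyquist).
#' @param orientation_deg mean striation-normal direction in degrees, wrapped
#'   to (-90, 90]. With the default 0 the striation normal lies along the
#'   image x (column) axis, i.e. band lines run vertically.
#' @param dispersion_deg angular standard deviation (degrees, >= 0) of the
#'   smoothly varying local orientation field.
#' @param pixel_size micrometres per pixel.
#' @param shape integer vector `c(rows, cols)`, each >= 64.
#' @param snr ratio of the banded signal's peak amplitude to the noise
#'   standard deviation; `Inf` for noise-free.
#' @param seed integer seed.
#' @return An object of class `striated_image_spec`.
#' @export
striated_image_spec <- function(spacing, orientation_deg = 0,
                                dispersion_deg = 0, pixel_size = 0.1,
                                shape = c(128L, 128L), snr = Inf, seed = 1L) {
  check_scalar(spacing, "spacing", lower = 0, strict_lower = TRUE)
  check_scalar(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_scalar(dispersion_deg, "dispersion_deg", lower = 0)
  check_scalar(snr, "snr", lower = 0, strict_lower = TRUE, allow_inf = TRUE)
  if (spacing <= 2 * pixel_size) {
    abort_cmq(sprintf(
      "spacing (%g um) must exceed 2 * pixel_size (%g um): band period below the Nyquist limit would alias",
      spacing, 2 * pixel_size), "cmquant_aliasing")
  }
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 64L)) {
    abort_cmq("`shape` must be c(rows, cols) with both dimensions >= 64",
              "cmquant_invalid_spec")
  }
  structure(list(spacing = spacing,
                 orientation_deg = wrap_orientation(orientation_deg),
                 dispersion_deg = dispersion_deg, pixel_size = pixel_size,
                 shape = shape, snr = snr, seed = as.integer(seed)),
            class = "striated_image_spec")
}

# Render one banded frame. `spacing` may differ per call (contraction movies);
# the orientation field and noise are drawn from the current RNG state.
render_banded_frame <- function(nr, nc, spacing, orientation_deg, pixel_size,
                                angle_field = NULL, noise_sd = 0,
                                envelope = TRUE) {
  x <- (seq_len(nc) - (nc + 1) / 2) * pixel_size  # um, columns
  y <- (seq_len(nr) - (nr + 1) / 2) * pixel_size  # um, rows
  X <- matrix(x, nr, nc, byrow = TRUE)
  Y <- matrix(y, nr, nc)
  theta <- (orientation_deg + if (is.null(angle_field)) 0 else angle_field) *
    pi / 180
  u <- X * cos(theta) + Y * sin(theta)
  img <- 0.5 + 0.5 * cos(2 * pi * u / spacing)
  if (envelope) {
    img <- img * (tukey_window(nr, 0.2) %o% rep(1, nc)) *
      (rep(1, nr) %o% tukey_window(nc, 0.2))
  }
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd),
                                        nr, nc)
  img
}

# Cosine-tapered (Tukey) window: flat centre, smooth fall-off at the edges.
tukey_window <- function(n, alpha) {
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  edge <- alpha / 2
  lo <- t < edge
  hi <- t > 1 - edge
  w[lo] <- 0.5 * (1 + cos(pi * (t[lo] / edge - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((t[hi] - 1 + edge) / edge)))
  w
}

# Smoothly varying local-angle field with circular SD `dispersion_deg`:
# low-pass-filtered white noise rescaled to the target spread, mimicking
# coherent sarcomere bundles rather than per-pixel jitter.
sample_angle_field <- function(nr, nc, dispersion_deg, smooth_sigma = 8) {
  if (dispersion_deg <= 0) return(NULL)
  f <- matrix(stats::rnorm(nr * nc), nr, nc)
  f <- as.matrix(EBImage::gblur(EBImage::Image(f), sigma = smooth_sigma))
  s <- stats::sd(as.vector(f))
  if (s < .Machine$double.eps) return(matrix(0, nr, nc))
  f * (dispersion_deg / s)
}

#' Generate a synthetic striated image
#'
#' @param spec a [striated_image_spec()].
#' @return A list with `image` (rows x cols numeric matrix of intensities)
#'   and `truth` (the generating parameters).
#' @export
#' @examples
#' img <- gen_striated_image(striated_image_spec(spacing = 2, seed = 7))
#' dim(img$image)
gen_striated_image <- function(spec) {
  stopifnot(inherits(spec, "striated_image_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  noise_sd <- if (is.finite(spec$snr)) 0.5 / spec$snr else 0
  img <- with_seed(spec$seed, {
    af <- sample_angle_field(nr, nc, spec$dispersion_deg)
    render_banded_frame(nr, nc, spec$spacing, spec$orientation_deg,
                        spec$pixel_size, angle_field = af,
                        noise_sd = noise_sd)
  })
  list(image = img, truth = unclass(spec))
}

#' Specification of a paced fluorescence/contraction time series
#'
#' Defaults follow a 1 Hz field-stimulation protocol sampled every 20 ms.
#'
#' @param duration recording length in seconds.
#' @param dt sampling interval in seconds (> 0).
#' @param pacing_hz stimulation frequency in Hz; the pacing period
#'   `1/pacing_hz` must exceed `rise_time`.
#' @param baseline resting fluorescence, arbitrary units (> 0).
#' @param amplitude peak delta-F/F0 of each transient (dimensionless, >= 0).
#' @param rise_time linear rise duration in seconds.
#' @param decay_tau exponential decay constant in seconds (> 0).
#' @param noise_sd additive Gaussian noise SD in raw fluorescence units.
#' @param seed integer seed.
#' @return An object of class `trace_spec`.
#' @export
trace_spec <- function(duration = 10, dt = 0.02, pacing_hz = 1,
                       baseline = 100, amplitude = 1.5, rise_time = 0.1,
                       decay_tau = 0.15, noise_sd = 0, seed = 1L) {
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  check_scalar(pacing_hz, "pacing_hz", lower = 0, strict_lower = TRUE)
  check_scalar(baseline, "baseline", lower = 0, strict_lower = TRUE)
  check_scalar(amplitude, "amplitude", lower = 0)
  check_scalar(rise_time, "rise_time", lower = 0)
  check_scalar(decay_tau, "decay_tau", lower = 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  if (1 / pacing_hz <= rise_time) {
    abort_cmq("pacing period 1/pacing_hz must exceed rise_time",
              "cmquant_invalid_spec")
  }
  structure(list(duration = duration, dt = dt, pacing_hz = pacing_hz,
                 baseline = baseline, amplitude = amplitude,
                 rise_time = rise_time, decay_tau = decay_tau,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "trace_spec")
}

# Normalized transient shape: linear rise 0 -> 1 over rise_time from each
# stimulus, then exponential decay; one transient per pacing period.
transient_shape <- function(times, pacing_hz, rise_time, decay_tau) {
  tau <- times %% (1 / pacing_hz)
  ifelse(tau < rise_time,
         if (rise_time > 0) tau / rise_time else 1,
         exp(-(tau - rise_time) / decay_tau))
}

#' Generate a synthetic calcium fluorescence trace
#'
#' Raw trace = `baseline * (1 + amplitude * s(t)) + noise`, where `s(t)` is a
#' linear rise over `rise_time` followed by exponential decay with
#' `decay_tau`, one transient per pacing period starting at t = 0.
#'
#' @param spec a [trace_spec()].
#' @return List with `trace` (data.frame: time, intensity) and `truth`
#'   (generating parameters plus the noise-free `dff_true` vector).
#' @export
gen_calcium_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  times <- seq(0, spec$duration - spec$dt / 2, by = spec$dt)
  s <- transient_shape(times, spec$pacing_hz, spec$rise_time, spec$decay_tau)
  dff_true <- spec$amplitude * s
  raw <- spec$baseline * (1 + dff_true)
  if (spec$noise_sd > 0) {
    raw <- with_seed(spec$seed, raw + stats::rnorm(length(raw), 0,
                                                   spec$noise_sd))
  }
  list(trace = data.frame(time = times, intensity = raw),
       truth = c(unclass(spec), list(dff_true = dff_true)))
}

# Raised-cosine contraction pulse with a 200 ms duty per pacing cycle:
# 0 at diastole, 1 at peak systole (pulse centre).
contraction_waveform <- function(times, pacing_hz, duty = 0.2) {
  tau <- times %% (1 / pacing_hz)
  ifelse(tau < duty, 0.5 * (1 - cos(2 * pi * tau / duty)), 0)
}

#' Generate a synthetic paced contraction movie
#'
#' Each frame is a noise-free-or-noisy banded image whose band spacing follows
#' a raised-cosine pacing waveform between the resting (diastolic) and
#' systolic sarcomere lengths.
#'
#' @param resting_length diastolic sarcomere length, micrometres.
#' @param systolic_length peak-systolic sarcomere length, micrometres;
#'   `0 < systolic_length <= resting_length` and above the Nyquist limit.
#' @param spec a [trace_spec()] supplying duration, dt, pacing and noise
#'   (`noise_sd` is interpreted in image-intensity units).
#' @param pixel_size micrometres per pixel.
#' @param shape frame dimensions `c(rows, cols)`.
#' @return List with `stack` (time x rows x cols array), `times`, and `truth`
#'   (including the generating per-frame `lengths`).
#' @export
gen_contraction_movie <- function(resting_length, systolic_length, spec,
                                  pixel_size = 0.1, shape = c(64L, 256L)) {
  stopifnot(inherits(spec, "trace_spec"))
  check_scalar(resting_length, "resting_length", lower = 0,
               strict_lower = TRUE)
  check_scalar(systolic_length, "systolic_length", lower = 0,
               strict_lower = TRUE)
  if (systolic_length > resting_length) {
    abort_cmq("systolic_length must not exceed resting_length",
              "cmquant_invalid_spec")
  }
  if (systolic_length <= 2 * pixel_size) {
    abort_cmq("systolic_length must exceed 2 * pixel_size (aliasing)",
              "cmquant_aliasing")
  }
  times <- seq(0, spec$duration - spec$dt / 2, by = spec$dt)
  w <- contraction_waveform(times, spec$pacing_hz)
  lengths <- resting_length - (resting_length - systolic_length) * w
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  stack <- with_seed(spec$seed, {
    arr <- array(0, dim = c(length(times), nr, nc))
    for (i in seq_along(times)) {
      arr[i, , ] <- render_banded_frame(nr, nc, lengths[i], 0, pixel_size,
                                        noise_sd = spec$noise_sd,
                                        envelope = FALSE)
    }
    arr
  })
  list(stack = stack, times = times,
       truth = list(resting_length = resting_length,
                    systolic_length = systolic_length,
                    pacing_hz = spec$pacing_hz, dt = spec$dt,
                    pixel_size = pixel_size, lengths = lengths,
                    percent_shortening =
                      (resting_length - systolic_length) / resting_length * 100,
                    seed = spec$seed))
}

#' Specification of a synthetic mitochondrial stress-test OCR series
#'
#' Encodes the four-phase Seahorse-style schedule (baseline, oligomycin,
#' FCCP, rotenone/antimycin A). The generator enforces the conservation
#' identity the partition assumes:
#' `atp_linked_true + proton_leak_true + nonmito_true = basal_true`.
#'
#' @param basal_true,atp_linked_true,proton_leak_true,maximal_true,nonmito_true
#'   generating rates in pmol O2/min (all >= 0).
#' @param n_measurements_per_phase measurements per phase (instrument default
#'   3).
#' @param noise_sd additive Gaussian noise SD, pmol O2/min.
#' @param seed integer seed.
#' @return An object of class `ocr_spec`.
#' @export
ocr_spec <- function(basal_true, atp_linked_true, proton_leak_true,
                     maximal_true, nonmito_true,
                     n_measurements_per_phase = 3L, noise_sd = 0, seed = 1L) {
  for (nm in c("basal_true", "atp_linked_true", "proton_leak_true",
               "maximal_true", "nonmito_true")) {
    check_scalar(get(nm), nm, lower = 0)
  }
  check_scalar(noise_sd, "noise_sd", lower = 0)
  if (abs(atp_linked_true + proton_leak_true + nonmito_true - basal_true) >
      1e-9 * max(1, basal_true)) {
    abort_cmq(paste("OCR conservation violated:",
                    "atp_linked_true + proton_leak_true + nonmito_true",
                    "must equal basal_true"), "cmquant_invalid_spec")
  }
  if (maximal_true < basal_true - nonmito_true - 1e-9) {
    abort_cmq("maximal_true must be >= basal_true - nonmito_true",
              "cmquant_invalid_spec")
  }
  n <- as.integer(n_measurements_per_phase)
  if (n < 1L) abort_cmq("n_measurements_per_phase must be >= 1",
                        "cmquant_invalid_spec")
  structure(list(basal_true = basal_true, atp_linked_true = atp_linked_true,
                 proton_leak_true = proton_leak_true,
                 maximal_true = maximal_true, nonmito_true = nonmito_true,
                 n_measurements_per_phase = n, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "ocr_spec")
}

#' Generate a synthetic OCR series with four injection phases
#'
#' Phase plateau means are `basal_true`,
#' `proton_leak_true + nonmito_true` (post-oligomycin), `maximal_true`
#' (post-FCCP) and `nonmito_true` (post-rotenone/antimycin A).
#'
#' @param spec an [ocr_spec()].
#' @param measurement_interval minutes between measurements (default 6.5, the
#'   usual mix/wait/measure cycle length).
#' @return List with `series` (data.frame: time, ocr), `injections`
#'   (data.frame: event, time) and `truth`.
#' @export
gen_ocr_series <- function(spec, measurement_interval = 6.5) {
  stopifnot(inherits(spec, "ocr_spec"))
  n <- spec$n_measurements_per_phase
  plateaus <- c(spec$basal_true,
                spec$proton_leak_true + spec$nonmito_true,
                spec$maximal_true,
                spec$nonmito_true)
  times <- seq_len(4L * n) * measurement_interval
  ocr <- rep(plateaus, each = n)
  if (spec$noise_sd > 0) {
    ocr <- with_seed(spec$seed,
                     ocr + stats::rnorm(length(ocr), 0, spec$noise_sd))
  }
  inj <- data.frame(
    event = c("oligomycin", "FCCP", "rotenone_antimycin"),
    time = (c(1, 2, 3) * n + 0.5) * measurement_interval)
  list(series = data.frame(time = times, ocr = ocr),
       injections = inj, truth = unclass(spec))
}

#' Generate a synthetic labelled cell population with nuclei
#'
#' Places non-overlapping rotated elliptical cells on a blank canvas and one
#' or two elliptical nuclei inside each (binuclear with probability
#' `binuclear_fraction`). Cells are kept clear of the image border.
#'
#' @param n_cells number of cells to place.
#' @param geometry_params list with `length_mean`, `length_sd`, `width_mean`,
#'   `width_sd` (micrometres). Defaults emulate day-28 PSC-CM geometry.
#' @param binuclear_fraction probability a cell carries two nuclei, in
#'   `[0, 1]`.
#' @param seed integer seed.
#' @param pixel_size micrometres per pixel.
#' @param shape canvas `c(rows, cols)` in pixels, or `NULL` to size the
#'   canvas automatically so cells occupy roughly 12 percent of it.
#' @param max_attempts placement attempts per cell before giving up.
#' @return List with `cell_mask` and `nuclei_mask` (integer label matrices,
#'   background 0) and `truth` (per-cell data.frame: cell_id, length_um,
#'   width_um, area_um2, orientation_deg, n_nuclei).
#' @export
gen_cell_population <- function(n_cells,
                                geometry_params = list(length_mean = 45,
                                                       length_sd = 8,
                                                       width_mean = 16,
                                                       width_sd = 3),
                                binuclear_fraction = 0.5, seed = 1L,
                                pixel_size = 1, shape = NULL,
                                max_attempts = 500L) {
  check_scalar(binuclear_fraction, "binuclear_fraction", lower = 0, upper = 1)
  stopifnot(n_cells >= 1)
  gp <- geometry_params
  mean_area_px <- pi * (gp$length_mean / 2) * (gp$width_mean / 2) /
    pixel_size^2
  if (is.null(shape)) {
    side <- ceiling(sqrt(n_cells * mean_area_px / 0.12))
    shape <- c(side, side)
  }
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])

  with_seed(seed, {
    cell_mask <- matrix(0L, nr, nc)
    nuclei_mask <- matrix(0L, nr, nc)
    truth <- vector("list", n_cells)
    nuc_label <- 0L
    for (id in seq_len(n_cells)) {
      len <- max(gp$width_mean, stats::rnorm(1, gp$length_mean, gp$length_sd))
      wid <- max(4 * pixel_size, stats::rnorm(1, gp$width_mean, gp$width_sd))
      wid <- min(wid, len)  # aspect ratio >= 1
      a <- len / 2 / pixel_size
      b <- wid / 2 / pixel_size
      phi <- stats::runif(1, -pi / 2, pi / 2)
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        margin <- ceiling(a) + 3
        if (2 * margin >= min(nr, nc)) break
        cy <- stats::runif(1, margin, nr - margin)
        cx <- stats::runif(1, margin, nc - margin)
        px <- ellipse_pixels(cy, cx, a + 2, b + 2, phi, nr, nc)
        if (all(cell_mask[px$idx] == 0L)) {
          core <- ellipse_pixels(cy, cx, a, b, phi, nr, nc)
          cell_mask[core$idx] <- id
          is_bi <- stats::runif(1) < binuclear_fraction
          n_nuc <- if (is_bi) 2L else 1L
          offs <- if (is_bi) c(-0.35, 0.35) * a else 0
          for (o in offs) {
            nuc_label <- nuc_label + 1L
            ncy <- cy + o * sin(phi)
            ncx <- cx + o * cos(phi)
            npx <- ellipse_pixels(ncy, ncx, min(0.25 * a, 0.6 * b),
                                  0.5 * b, phi, nr, nc)
            nuclei_mask[npx$idx] <- nuc_label
          }
          truth[[id]] <- data.frame(
            cell_id = id, length_um = 2 * a * pixel_size,
            width_um = 2 * b * pixel_size,
            area_um2 = nrow(core$idx) * pixel_size^2,
            orientation_deg = phi * 180 / pi, n_nuclei = n_nuc)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort_cmq(sprintf(
          "could not place cell %d of %d without overlap in a %dx%d canvas",
          id, n_cells, nr, nc), "cmquant_placement_failure")
      }
    }
    list(cell_mask = cell_mask, nuclei_mask = nuclei_mask,
         truth = do.call(rbind, truth))
  })
}

# Linear indices of pixels inside a rotated ellipse, clipped to the canvas.
ellipse_pixels <- function(cy, cx, a, b, phi, nr, nc) {
  r0 <- max(1L, floor(cy - a)); r1 <- min(nr, ceiling(cy + a))
  c0 <- max(1L, floor(cx - a)); c1 <- min(nc, ceiling(cx + a))
  rows <- r0:r1; cols <- c0:c1
  R <- matrix(rows, length(rows), length(cols)) - cy
  C <- matrix(cols, length(rows), length(cols), byrow = TRUE) - cx
  u <- C * cos(phi) + R * sin(phi)
  v <- -C * sin(phi) + R * cos(phi)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx_r <- matrix(rows, length(rows), length(cols))[inside]
  idx_c <- matrix(cols, length(rows), length(cols), byrow = TRUE)[inside]
  list(idx = cbind(idx_r, idx_c))
}

#' Generate a synthetic two-population flow-cytometry sample
#'
#' Event intensities are drawn from a two-component log-normal mixture
#' (locations and scales on the log10 scale), emulating a negative
#' autofluorescence population and a reporter-positive population.
#'
#' @param n_events number of events.
#' @param positive_fraction proportion of events from the positive component,
#'   in `[0, 1]`.
#' @param neg_location,neg_scale log10-intensity mean and SD of the negative
#'   population.
#' @param pos_location,pos_scale log10-intensity mean and SD of the positive
#'   population; `pos_location` must exceed `neg_location`.
#' @param seed integer seed.
#' @return List with `events` (data.frame: event_id, intensity, label) and
#'   `truth`.
#' @export
gen_cytometry_sample <- function(n_events, positive_fraction,
                                 neg_location = 1.5, neg_scale = 0.25,
                                 pos_location = 3.0, pos_scale = 0.3,
                                 seed = 1L) {
  check_scalar(positive_fraction, "positive_fraction", lower = 0, upper = 1)
  if (pos_location <= neg_location) {
    abort_cmq("pos_location must exceed neg_location",
              "cmquant_invalid_spec")
  }
  with_seed(seed, {
    lab <- stats::rbinom(n_events, 1L, positive_fraction)
    z <- ifelse(lab == 1L,
                stats::rnorm(n_events, pos_location, pos_scale),
                stats::rnorm(n_events, neg_location, neg_scale))
    list(events = data.frame(event_id = seq_len(n_events),
                             intensity = 10^z,
                             label = ifelse(lab == 1L, "positive",
                                            "negative")),
         truth = list(n_events = n_events,
                      positive_fraction = positive_fraction,
                      neg_location = neg_location, neg_scale = neg_scale,
                      pos_location = pos_location, pos_scale = pos_scale,
                      seed = seed))
  })
}
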