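# Generators: determinism, ground-truth round trips, and input validation.

test_that("striated image generation is bit-reproducible for a fixed seed", {
  spec <- striated_image_spec(spacing = 2, dispersion_deg = 15, snr = 5,
                              seed = 42L)
  a <- gen_striated_image(spec)
  b <- gen_striated_image(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$spacing, 2)
})

test_that("generation does not disturb the global RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_striated_image(striated_image_spec(spacing = 2, seed = 7L)))
  expect_identical(.Random.seed, before)
})

test_that("noise-free striated image has its spectral peak at 1/spacing", {
  g <- gen_striated_image(striated_image_spec(spacing = 2, pixel_size = 0.1,
                                              shape = c(128L, 256L),
                                              seed = 1L))
  prof <- extract_line_profile(g$image, c(64, 2), c(64, 253),
                               width_px = 1L, pixel_size = 0.1)
  est <- estimate_sarcomere_length(prof)
  expect_identical(est$status, "ok")
  # dominant 1-D spatial frequency 0.5 um^-1 <=> length 2.0 um
  expect_lt(abs(1 / est$length - 0.5), 0.01)
})

test_that("dispersion lowers the alignment index", {
  mk <- function(disp) {
    g <- gen_striated_image(striated_image_spec(
      spacing = 2, orientation_deg = 0, dispersion_deg = disp, seed = 3L))
    alignment_index(orientation_histogram(g$image))$index
  }
  expect_gt(mk(0), mk(45))
})

test_that("sub-Nyquist spacing is rejected", {
  expect_error(striated_image_spec(spacing = 0.15, pixel_size = 0.1),
               class = "cmquant_aliasing")
  expect_error(striated_image_spec(spacing = 2, shape = c(32L, 128L)),
               class = "cmquant_invalid_spec")
})

test_that("calcium trace generator honours amplitude 0 and determinism", {
  flat <- gen_calcium_trace(trace_spec(amplitude = 0, noise_sd = 2,
                                       seed = 5L))
  expect_lt(abs(mean(flat$trace$intensity) - 100), 1)
  expect_identical(flat$truth$dff_true, rep(0, nrow(flat$trace)))
  a <- gen_calcium_trace(trace_spec(noise_sd = 3, seed = 11L))
  b <- gen_calcium_trace(trace_spec(noise_sd = 3, seed = 11L))
  expect_identical(a$trace, b$trace)
})

test_that("trace spec rejects a pacing period shorter than the rise time", {
  expect_error(trace_spec(pacing_hz = 4, rise_time = 0.3),
               class = "cmquant_invalid_spec")
})

test_that("contraction movie with equal lengths yields identical frames", {
  spec <- trace_spec(duration = 1, dt = 0.1, seed = 2L)
  m <- gen_contraction_movie(2.0, 2.0, spec, pixel_size = 0.1)
  expect_identical(m$stack[1, , ], m$stack[5, , ])
  expect_error(gen_contraction_movie(2.0, 2.1, spec),
               class = "cmquant_invalid_spec")
  expect_error(gen_contraction_movie(2.0, 0.15, spec, pixel_size = 0.1),
               class = "cmquant_aliasing")
})

test_that("OCR generator emits the documented plateaus and counts", {
  spec <- ocr_spec(100, 60, 30, 150, 10, n_measurements_per_phase = 3L)
  g <- gen_ocr_series(spec)
  expect_identical(nrow(g$series), 12L)
  expect_identical(unique(g$series$ocr), c(100, 40, 150, 10))
  expect_identical(as.character(g$injections$event),
                   c("oligomycin", "FCCP", "rotenone_antimycin"))
})

test_that("OCR spec enforces the conservation identity", {
  expect_error(ocr_spec(100, 60, 30, 150, 20),
               class = "cmquant_invalid_spec")
  expect_error(ocr_spec(100, 60, 30, 80, 10),
               class = "cmquant_invalid_spec")
})

test_that("cell population nuclei counts follow binuclear_fraction 0 and 1", {
  mono <- gen_cell_population(12, binuclear_fraction = 0, seed = 4L)
  expect_true(all(mono$truth$n_nuclei == 1L))
  bi <- gen_cell_population(12, binuclear_fraction = 1, seed = 4L)
  expect_true(all(bi$truth$n_nuclei == 2L))
  # every nucleus sits inside its cell and labels are 1..n
  expect_identical(sort(unique(as.integer(bi$cell_mask[bi$cell_mask > 0]))),
                   1:12)
  inside <- bi$cell_mask[bi$nuclei_mask > 0]
  expect_true(all(inside > 0L))
})

test_that("impossible placement raises a placement failure", {
  expect_error(gen_cell_population(50, shape = c(80L, 80L), seed = 1L),
               class = "cmquant_placement_failure")
})

test_that("cytometry sample is reproducible and labelled", {
  a <- gen_cytometry_sample(500, 0.3, seed = 9L)
  b <- gen_cytometry_sample(500, 0.3, seed = 9L)
  expect_identical(a$events, b$events)
  expect_identical(mean(a$events$label == "positive"),
                   a$truth$positive_fraction, tolerance = 0.1)
  expect_error(gen_cytometry_sample(10, 0.5, neg_location = 3,
                                    pos_location = 2),
               class = "cmquant_invalid_spec")
})
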