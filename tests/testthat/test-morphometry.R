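# Per-cell geometry, binucleation classification and group tables.

test_that("a 10x10 pixel square measures 100 um^2 with circularity <= 1", {
  m <- matrix(0L, 32, 32); m[11:20, 11:20] <- 1L
  d <- measure_cells(m, pixel_size = 1)
  expect_equal(d$area, 100)
  expect_lte(d$circularity, 1 + 0.05)
  expect_gt(d$circularity, 0)
  expect_false(d$border_touching)
})

test_that("a rasterized disk has circularity within [0.9, 1.05]", {
  d <- measure_cells(raster_disk(20, 64))
  expect_gte(d$circularity, 0.9)
  expect_lte(d$circularity, 1.05)
  expect_lt(abs(d$area - pi * 20^2) / (pi * 20^2), 0.02)
})

test_that("ellipse axes match the moments of the rasterized region", {
  # semi-axes 20/5 px; frozen oracle values from an independent
  # moments-of-region implementation (scikit-image regionprops) on the
  # identical rasterization: major 40.9784, minor 9.6711
  d <- measure_cells(raster_ellipse(20, 5, 64))
  expect_equal(d$length, 40.9784, tolerance = 1e-4)
  expect_equal(d$width, 9.6711, tolerance = 1e-4)
  expect_equal(d$aspect_ratio, 4.2372, tolerance = 1e-3)
  # at finer rasterization the discretization bias shrinks and the ratio
  # approaches the analytic 4.0
  d2 <- measure_cells(raster_ellipse(40, 10, 128))
  expect_lt(abs(d2$aspect_ratio - 4) / 4, 0.05)
})

test_that("area and perimeter scale as s^2 and s under upscaling", {
  small <- measure_cells(raster_disk(10, 32))
  big <- measure_cells(raster_disk(20, 64))
  expect_lt(abs(big$area / small$area - 4) / 4, 0.03)
  expect_lt(abs(big$perimeter / small$perimeter - 2) / 2, 0.03)
})

test_that("feret axes are available and at least as long as ellipse axes", {
  m <- raster_ellipse(20, 5, 64)
  fe <- measure_cells(m, axis_method = "feret")
  expect_gte(fe$length, 40)       # max Feret of a 40-px-long region
  expect_gte(fe$aspect_ratio, 1)
})

test_that("border-touching cells are flagged", {
  m <- matrix(0L, 64, 64); m[1:10, 5:14] <- 1L; m[30:39, 30:39] <- 2L
  d <- measure_cells(m)
  expect_identical(d$border_touching, c(TRUE, FALSE))
  expect_error(measure_cells(matrix(0L, 16, 16)),
               class = "cmquant_empty_mask")
})

test_that("nuclearity classification assigns by majority overlap", {
  cells <- matrix(0L, 64, 64); cells[10:40, 10:40] <- 1L
  nuc <- matrix(0L, 64, 64)
  nuc[15:20, 15:20] <- 1L; nuc[30:35, 30:35] <- 2L
  d <- classify_nuclearity(cells, nuc)
  expect_identical(d$n_nuclei, 2L)
  expect_identical(d$nuclearity, "binuclear")
  nuc2 <- matrix(0L, 64, 64); nuc2[15:20, 15:20] <- 1L
  expect_identical(classify_nuclearity(cells, nuc2)$nuclearity,
                   "mononuclear")
})

test_that("orphan nuclei are reported unassigned, shape mismatch errors", {
  cells <- matrix(0L, 64, 64); cells[10:20, 10:20] <- 1L
  nuc <- matrix(0L, 64, 64); nuc[12:15, 12:15] <- 1L; nuc[50:55, 50:55] <- 2L
  expect_message(d <- classify_nuclearity(cells, nuc), "unassigned")
  expect_identical(attr(d, "unassigned_nuclei"), 2L)
  expect_identical(d$n_nuclei, 1L)
  expect_error(classify_nuclearity(cells, matrix(0L, 32, 32)),
               class = "cmquant_invalid_mask")
})

test_that("nuclearity table reproduces hand-computed chi-square results", {
  mk <- function(n_mono, n_bi) {
    data.frame(nuclearity = rep(c("mononuclear", "binuclear"),
                                c(n_mono, n_bi)))
  }
  same <- nuclearity_table(list(a = mk(50, 50), b = mk(50, 50)))
  expect_equal(same$statistic, 0)
  skewed <- nuclearity_table(list(a = mk(90, 10), b = mk(10, 90)))
  expect_equal(skewed$statistic, 128)
  expect_equal(skewed$df, 1)
  expect_lt(skewed$p_value, 1e-10)
  three <- nuclearity_table(list(a = mk(40, 60), b = mk(40, 60),
                                 c = mk(40, 60)))
  expect_gt(three$p_value, 0.999)
  # counts conserved
  expect_identical(sum(skewed$table), 200)
})

test_that("degenerate tables error rather than returning NaN", {
  mk <- function(n_mono, n_bi) {
    data.frame(nuclearity = rep(c("mononuclear", "binuclear"),
                                c(n_mono, n_bi)))
  }
  expect_error(nuclearity_table(list(a = mk(10, 0), b = mk(20, 0))),
               class = "cmquant_degenerate_table")
  expect_error(nuclearity_table(list(a = mk(10, 10))))
})

test_that("population generator truth is recovered by measurement", {
  pop <- gen_cell_population(25, seed = 17L)
  d <- measure_cells(pop$cell_mask)
  d <- d[!d$border_touching, ]
  truth <- pop$truth[match(d$cell_id, pop$truth$cell_id), ]
  expect_lt(median(abs(d$length - truth$length_um) / truth$length_um), 0.05)
  expect_identical(d$area, truth$area_um2)
})
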