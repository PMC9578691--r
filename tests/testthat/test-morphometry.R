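test_that("blank channel segments to zero structures", {
  img <- labeled_image(list(dapi = matrix(0, 50, 50)), pixel_size = 1)
  lab <- segment_structures(img, "dapi")
  expect_true(all(lab == 0))
  expect_error(segment_structures(img, "nope"), "channel 'nope' not found")
})

test_that("a single synthetic body is recovered with area within 5% of truth", {
  sim <- simulate_gastruloid_image(image_sim_params(
    body_semi_axes = c(120, 50), pixel_size = 2, seed = 31))
  lab <- segment_structures(sim$image, "dapi")
  expect_identical(max(lab), 1L)
  m <- measure_structure(lab, 1, sim$image$pixel_size)
  expect_lt(abs(m$area - sim$truth$true_area) / sim$truth$true_area, 0.05)
})

test_that("two bodies joined by a narrow neck split into two structures", {
  m <- matrix(0, 100, 220)
  rr <- row(m) - 1; cc <- col(m) - 1
  blob <- (((cc - 55) / 45)^2 + ((rr - 50) / 32)^2 <= 1) |
          (((cc - 160) / 45)^2 + ((rr - 50) / 32)^2 <= 1)
  img <- labeled_image(list(dapi = blob * 500), pixel_size = 1)
  lab <- segment_structures(img, "dapi", smooth_sigma = 0, min_area = 500)
  expect_identical(max(lab), 2L)
})

test_that("closed-form shape oracles hold for disk, square and ellipse", {
  ps <- 1
  lab <- raster_disk(100)
  m <- measure_structure(lab, 1, ps)
  expect_equal(m$elongation_index, 1.0, tolerance = 0.03)
  circ <- sqrt(4 * (m$area / ps^2) / (pi * (m$feret_max / ps)^2))
  expect_equal(circ, 1.0, tolerance = 0.02)

  s <- 200
  m <- measure_structure(raster_square(s), 1, ps)
  expect_equal(m$feret_max, s * sqrt(2), tolerance = 0.02)
  circ <- sqrt(4 * (m$area / ps^2) / (pi * (m$feret_max / ps)^2))
  expect_equal(circ, sqrt(2 / pi), tolerance = 0.02)

  m <- measure_structure(raster_ellipse(150, 50), 1, ps)
  expect_equal(m$elongation_index, 3.0, tolerance = 0.03)
})

test_that("single-pixel objects are rejected as degenerate", {
  lab <- matrix(0L, 10, 10); lab[5, 5] <- 1L
  expect_error(measure_structure(lab, 1, 1), "degenerate object")
  expect_error(measure_structure(lab, 2, 1), "not present")
})

test_that("doubling pixel size doubles Feret, quadruples area, fixes ratios", {
  lab <- raster_ellipse(80, 30)
  m1 <- measure_structure(lab, 1, 1)
  m2 <- measure_structure(lab, 1, 2)
  expect_equal(m2$feret_max, 2 * m1$feret_max)
  expect_equal(m2$feret_min, 2 * m1$feret_min)
  expect_equal(m2$area, 4 * m1$area)
  expect_equal(m2$elongation_index, m1$elongation_index)
})

test_that("structure labels partition the segmented foreground", {
  sim <- simulate_gastruloid_image(image_sim_params(seed = 33))
  lab <- segment_structures(sim$image, "dapi")
  ms <- measure_structures(lab, 1)
  expect_lte(sum(ms$area), sum(lab > 0))   # pixel counts at pixel_size 1
  expect_equal(sum(ms$area), sum(lab > 0)) # no filtering inside measurement
  expect_true(all(ms$feret_max >= ms$feret_min))
  expect_true(all(ms$elongation_index >= 1))
})

test_that("segmentation recovers area and elongation within 5% over seeds", {
  errs_area <- errs_ei <- numeric(0)
  for (s in 1:8) {
    sim <- simulate_gastruloid_image(image_sim_params(
      body_semi_axes = c(130, 50), pixel_size = 2, seed = 300 + s))
    lab <- segment_structures(sim$image, "dapi")
    main <- which.max(tabulate(lab[lab > 0]))
    m <- measure_structure(lab, main, sim$image$pixel_size)
    errs_area <- c(errs_area, abs(m$area - sim$truth$true_area) / sim$truth$true_area)
    ei_true <- sim$truth$true_feret_max / sim$truth$true_feret_min
    errs_ei <- c(errs_ei, abs(m$elongation_index - ei_true) / ei_true)
  }
  expect_lt(mean(errs_area), 0.05)
  expect_lt(mean(errs_ei), 0.05)
})

test_that("variance thresholding segments a textured object on a flat field", {
  set.seed(41)
  obj <- raster_disk(45, pad = 24) > 0
  x <- matrix(100, nrow(obj), ncol(obj))
  x[obj] <- 100 + rnorm(sum(obj), 0, 40)   # same mean, different texture
  img <- labeled_image(list(bf = x), pixel_size = 1)
  lab <- segment_structures(img, "bf", method = "variance", smooth_sigma = 0,
                            min_area = 2000)
  expect_gte(max(lab), 1)
  main <- which.max(tabulate(lab[lab > 0]))
  m <- measure_structure(lab, main, 1)
  expect_equal(m$area, sum(obj), tolerance = 0.25)
})

test_that("nucleus records carry area, circularity and intensity filters", {
  mk_disk <- function(m, r0, c0, rad, val) {
    m + val * ((row(m) - 1 - r0)^2 + (col(m) - 1 - c0)^2 <= rad^2)
  }
  dapi <- matrix(0, 150, 150)
  dapi <- mk_disk(dapi, 35, 35, 8, 100)    # area ~201 µm² -> passes
  dapi <- mk_disk(dapi, 100, 100, 3.6, 100) # area ~40 µm² -> too small
  gfp <- matrix(7, 150, 150)
  img <- labeled_image(list(dapi = dapi, gfp = gfp), pixel_size = 1)
  nuc <- quantify_nuclei(img, "dapi", smooth_sigma = 0, background_radius = 20)
  expect_identical(nrow(nuc), 2L)
  big <- nuc[which.max(nuc$area), ]; small <- nuc[which.min(nuc$area), ]
  expect_true(big$area >= 100 && big$area <= 1000)
  expect_true(big$passed_filters)
  expect_false(small$passed_filters)      # below the 100 µm² area rule
  # uniform channel: integrated/area equals the mean equals the pixel value
  expect_equal(big$norm_gfp, 7)
  expect_equal(big$mean_gfp, 7)
})

test_that("elongated slivers fail the circularity filter", {
  dapi <- matrix(0, 120, 120)
  dapi[58:62, 20:100] <- 100               # 5 x 81 px sliver, circularity ~0.3
  img <- labeled_image(list(dapi = dapi), pixel_size = 1)
  nuc <- quantify_nuclei(img, "dapi", measure_channels = character(0),
                         smooth_sigma = 0, background_radius = 30)
  expect_identical(nrow(nuc), 1L)
  expect_lt(nuc$circularity, 0.6)
  expect_false(nuc$passed_filters)
  expect_true(nuc$area >= 100 && nuc$area <= 1000)  # fails on shape alone
})

test_that("zero nuclei yield an empty record table", {
  img <- labeled_image(list(dapi = matrix(5, 40, 40)), pixel_size = 1)
  expect_identical(nrow(quantify_nuclei(img, "dapi")), 0L)
})
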