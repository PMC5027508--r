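test_that("ladder calibration interpolates exactly through knots", {
  two <- data.frame(pixel = c(100, 200), length = c(150, 50))
  cal <- fit_ladder(two)
  expect_equal(as.numeric(pixel_to_length(cal, 150)), 100)  # linear midpoint
  expect_equal(as.numeric(length_to_pixel(cal, 100)), 150)

  bands <- data.frame(pixel = c(50, 120, 210, 330, 480),
                      length = c(300, 200, 125, 75, 25))
  cal2 <- fit_ladder(bands)
  expect_equal(as.numeric(pixel_to_length(cal2, bands$pixel)), bands$length)
  expect_equal(as.numeric(length_to_pixel(cal2, bands$length)), bands$pixel)
  # round trip on and off the knots, monotone on the hull
  px <- seq(50, 480, by = 7)
  expect_equal(as.numeric(length_to_pixel(cal2, pixel_to_length(cal2, px))),
               px, tolerance = 1e-9)
  expect_true(all(diff(pixel_to_length(cal2, px)) < 0))

  expect_error(fit_ladder(data.frame(pixel = c(1, 2), length = c(5, 5))),
               "monotone")
  expect_error(fit_ladder(data.frame(pixel = 1, length = 5)), ">= 2")
})

test_that("queries beyond the knot hull extrapolate linearly and are flagged", {
  cal <- fit_ladder(data.frame(pixel = c(100, 200), length = c(150, 50)))
  out <- pixel_to_length(cal, c(50, 150, 250))
  expect_equal(attr(out, "extrapolated"), c(TRUE, FALSE, TRUE))
  expect_equal(as.numeric(out), c(200, 100, 0))
})

test_that("piecewise calibration tracks a log migration model within curvature error", {
  a <- 1475; b <- -250
  dense <- data.frame(length = seq(25, 300, by = 25))
  dense$pixel <- a + b * log(dense$length)
  dense <- dense[order(dense$pixel), ]
  cal <- fit_ladder(dense)
  px <- seq(min(dense$pixel), max(dense$pixel), length.out = 400)
  truth <- exp((px - a) / b)
  err <- max(abs(pixel_to_length(cal, px) - truth))
  # chord error of a convex model stays below one knot spacing
  expect_lt(err, 25 / 2)
  # the global-line variant is a coarser but monotone approximation
  calg <- fit_ladder(dense, method = "global")
  expect_gt(max(abs(pixel_to_length(calg, px) - truth)), err)
})

test_that("TP quantification recovers planted band-area fractions", {
  sim <- simulate_gel(gel_spec(data.frame(length = c(125, 250),
                                          area = c(30, 70),
                                          width = c(1, 2))))
  cal <- fit_ladder(sim$ladder)
  expect_equal(quantify_tp_fraction(sim$lane, cal), 30, tolerance = 0.005)
  # uniform rescaling of the lane leaves the percentage unchanged
  scaled <- lane_profile(sim$lane$density * 7.3)
  expect_equal(quantify_tp_fraction(scaled, cal),
               quantify_tp_fraction(sim$lane, cal), tolerance = 1e-12)
})

test_that("density below the total-window cutoff does not affect the TP fraction", {
  sim <- simulate_gel(gel_spec(data.frame(length = c(125, 250),
                                          area = c(30, 70),
                                          width = c(1, 2))))
  cal <- fit_ladder(sim$ladder)
  base <- quantify_tp_fraction(sim$lane, cal)
  # add a band well below the 100 nt marker (shorter fragments, higher px)
  with_small <- simulate_gel(gel_spec(data.frame(
    length = c(125, 250, 40), area = c(30, 70, 50), width = c(1, 2, 1))))
  expect_equal(quantify_tp_fraction(with_small$lane, cal), base,
               tolerance = 0.01)
  # a lane entirely within the TP window quantifies to 100%
  only_tp <- simulate_gel(gel_spec(data.frame(length = 125, area = 10,
                                              width = 1)))
  expect_equal(quantify_tp_fraction(only_tp$lane, cal), 100,
               tolerance = 0.005)
})

test_that("zero density and out-of-hull TP windows raise errors", {
  cal <- fit_ladder(data.frame(pixel = c(100, 200), length = c(150, 50)))
  flat <- lane_profile(rep(0, 300))
  expect_error(quantify_tp_fraction(flat, cal), "zero total density")
  wide <- quant_regions(tp_window = c(92, 400), lower_cutoff = 100)
  lane <- lane_profile(rep(1, 300))
  expect_error(quantify_tp_fraction(lane, cal, wide), "calibration hull")
})

test_that("lane normalization scales the window maximum to 1 and is idempotent", {
  sim <- simulate_gel(gel_spec(data.frame(length = c(125, 250),
                                          area = c(30, 70),
                                          width = c(1, 2))))
  cal <- fit_ladder(sim$ladder)
  norm <- normalize_profile(sim$lane, cal)
  len <- pixel_to_length(cal, seq_along(norm$density))
  expect_equal(max(norm$density[len >= 92 & len <= 140]), 1)
  norm2 <- normalize_profile(norm, cal)
  expect_equal(norm2$density, norm$density)
  const <- normalize_profile(lane_profile(rep(2, length(sim$lane$density))),
                             cal)
  expect_true(all(const$density == 1))
  expect_error(normalize_profile(lane_profile(rep(0, 1000)), cal),
               "zero maximum")
})

test_that("peak calling recovers planted band positions and separations", {
  one <- simulate_gel(gel_spec(data.frame(length = 125, area = 10,
                                          width = 0.5)))
  cal <- fit_ladder(one$ladder)
  pk <- call_peaks(normalize_profile(one$lane, cal), cal)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$length_nt, 125, tolerance = 0.01)

  expect_equal(nrow(call_peaks(lane_profile(rep(1, 100)), cal)), 0L)

  # two bands 3 nt apart resolve into peaks separated by 3 nt
  twin <- simulate_gel(gel_spec(data.frame(length = c(122, 125),
                                           area = c(10, 10),
                                           width = c(0.4, 0.4))))
  pk2 <- call_peaks(normalize_profile(twin$lane, cal), cal)
  expect_equal(nrow(pk2), 2L)
  expect_equal(abs(diff(pk2$length_nt)), 3, tolerance = 0.15)

  # optional 3'-end mapping through a configured TSS
  pk3 <- call_peaks(normalize_profile(one$lane, cal), cal, tss_rcrs = 407)
  expect_equal(pk3$end_rcrs, 283L)
})
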