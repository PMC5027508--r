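test_that("frequency matrices conserve totals and round-trip through TSV", {
  fm <- frequency_matrix(c(G5AG7 = 3L, G6AG7 = 10L, G13 = 2L),
                         continuous_range = 1:15)
  expect_equal(fm$total_hits, 15)
  expect_equal(sum(vapply(fm$counts, sum, 0)) + sum(fm$continuous),
               fm$total_hits)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_frequency_matrix(fm, path)
  back <- read_frequency_matrix(path)
  expect_equal(back$counts, fm$counts)
  expect_equal(back$continuous, fm$continuous)
  expect_error(frequency_matrix(c(G20AG1 = 1L)), "outside the matrix grid")
})

test_that("totals by total guanines pool anti-diagonals and conserve hits", {
  expect_equal(totals_by_total_g(frequency_matrix(c(G5AG7 = 10L))),
               c("12" = 10L))
  expect_equal(totals_by_total_g(frequency_matrix(c(G5AG7 = 1L, G6AG6 = 2L))),
               c("12" = 3L))
  fm <- random_matrix(seed = 31)
  expect_equal(sum(totals_by_total_g(fm)), fm$total_hits)
  # continuous counts join at their own length when requested
  fm2 <- frequency_matrix(c(G5AG7 = 1L, G12 = 4L), continuous_range = 1:12)
  expect_equal(totals_by_total_g(fm2, include_continuous = TRUE),
               c("12" = 5L))
})

test_that("sample skewness matches the spreadsheet estimator", {
  expect_equal(sample_skewness(c(1, 2, 3)), 0)
  expect_equal(sample_skewness(c(1, 2, 10)), 1.6523167403, tolerance = 1e-9)
  set.seed(32)
  for (i in 1:20) {
    x <- rnorm(sample(5:50, 1))
    # independent oracle: the type-2 estimator of e1071
    expect_equal(sample_skewness(x), e1071::skewness(x, type = 2),
                 tolerance = 1e-12)
    expect_equal(sample_skewness(-x), -sample_skewness(x),
                 tolerance = 1e-12)
  }
  expect_error(sample_skewness(c(1, 2)), "at least 3")
  expect_error(sample_skewness(c(2, 2, 2)), "zero-variance")
  # the moment estimator is exposed but distinct
  x <- c(1, 2, 10)
  expect_equal(sample_skewness(x, method = "moment"),
               mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5)
})

test_that("quadrant partition conserves hits and tallies axes separately", {
  pivot_only <- frequency_matrix(c(G6AG7 = 25L))
  q <- quadrant_counts(pivot_only)
  expect_equal(unname(q$strict["on_axes"]), 25L)
  expect_equal(sum(q$strict[1:4]), 0L)

  one_off <- frequency_matrix(c(G5AG8 = 7L))
  q2 <- quadrant_counts(one_off)
  expect_equal(unname(q2$strict["short_first_long_second"]), 7L)
  expect_equal(unname(q2$fractions["short_first_long_second"]), 1)

  fm <- random_matrix(m_range = 1:10, n_range = 1:10, seed = 33)
  q3 <- quadrant_counts(fm, pivot = c(5, 5))
  expect_equal(sum(q3$strict), q3$total)
  expect_equal(q3$total, fm$total_hits)
  expect_error(quadrant_counts(fm, pivot = c(40, 2)), "outside")
  expect_error(quadrant_counts(frequency_matrix(c(G13 = 5L),
                                                continuous_range = 1:13)),
               "no interrupted hits")
})

test_that("position spectrum pools counts by adenine position", {
  only <- frequency_matrix(c(G6AG7 = 50L))
  ps <- position_spectrum(only)
  expect_equal(ps$position, -1L)
  expect_equal(ps$fraction, 1)

  equal_runs <- frequency_matrix(c(G5AG5 = 4L, G7AG7 = 6L))
  expect_equal(position_spectrum(equal_runs)$position, 0L)

  fm <- random_matrix(seed = 34)
  ps2 <- position_spectrum(fm)
  expect_equal(sum(ps2$count), fm$total_hits)
  expect_equal(sum(ps2$fraction), 1)
})

test_that("cumulative TP curves sort by TP and expose window fractions", {
  one <- frequency_matrix(c(G5AG7 = 10L))
  tp <- tp_table("G5AG7", 17)
  cv <- cumulative_tp_curve(one, tp)
  expect_equal(nrow(cv), 1L)
  expect_equal(cv$cumulative_hit_fraction, 1)
  expect_equal(fraction_within(cv, 17, 43), 1)

  two <- frequency_matrix(c(G3AG9 = 5L, G7AG6 = 5L))
  tp2 <- tp_table(c("G3AG9", "G7AG6"), c(11, 17))
  cv2 <- cumulative_tp_curve(two, tp2)
  expect_equal(cv2$variant, c("G3AG9", "G7AG6"))  # ascending TP
  expect_equal(cv2$cumulative_hit_fraction, c(0.5, 1))
  expect_equal(fraction_within(cv2, 17, 43), 0.5)
  expect_equal(fraction_within(cv2, 0, 100), 1)
  expect_true(all(diff(cv2$cumulative_hit_fraction) >= 0))

  # occupied variants without a TP value are excluded with a warning
  three <- frequency_matrix(c(G3AG9 = 5L, G7AG6 = 5L, G2AG2 = 3L))
  expect_warning(cv3 <- cumulative_tp_curve(three, tp2), "G2AG2")
  expect_equal(attr(cv3, "excluded"), "G2AG2")
  expect_equal(sum(cv3$hit_count), 10L)
  expect_error(
    suppressWarnings(cumulative_tp_curve(frequency_matrix(c(G2AG2 = 1L)),
                                         tp2)),
    "no occupied variant")
})

test_that("a spectrum concentrated on common alleles reproduces the survey's structure", {
  # mass on {G5AG7, G6AG7, G6AG8, G6AG9}: all adenines at -1/-2, and the
  # short-first/long-second quadrant side dominates around pivot G6AG7
  fm <- frequency_matrix(c(G5AG7 = 13L, G6AG7 = 37L, G6AG8 = 35L,
                           G6AG9 = 10L))
  ps <- position_spectrum(fm)
  expect_setequal(ps$position, c(-2L, -1L))
  expect_gt(ps$fraction[ps$position == -1L], 0.8)
  q <- quadrant_counts(fm)
  expect_equal(unname(q$fractions["short_first_long_second"]), 1)
  expect_equal(unname(q$strict["long_first_short_second"]), 0L)
  expect_equal(unname(q$strict["both_short"]), 0L)
})

test_that("survey reports bundle the statistics and serialize to JSON", {
  fm <- frequency_matrix(c(G5AG7 = 13L, G6AG7 = 37L, G6AG8 = 35L,
                           G6AG9 = 10L, G13 = 5L),
                         continuous_range = 1:15)
  tp <- tp_table(c("G5AG7", "G6AG7", "G6AG8", "G6AG9", "G13"),
                 c(17, 34, 34, 40, 25))
  path <- withr::local_tempfile(fileext = ".json")
  rep <- survey_report(fm, tp = tp, path = path)
  expect_equal(rep$total_hits, 100)
  expect_equal(rep$continuous_hits, 5)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$total_hits, 100)
  expect_true("cumulative_curve" %in% names(parsed))
})
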