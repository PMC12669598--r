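test_that("acquisition stop rule halts exactly at the stop count", {
  h <- acquire_calibration(source_am241(2e4), detector_config(), seed = 1)
  expect_equal(max(h$counts), 50)            # default stop limit
  expect_false(attr(h, "timeout"))
  expect_lt(h$real_time, 60)

  h1 <- acquire_calibration(source_am241(2e4), detector_config(),
                            stop_count = 1, seed = 2)
  expect_equal(max(h1$counts), 1)
})

test_that("timeout behavior distinguishes usable and unusable acquisitions", {
  # zero-rate source, min_counts = 0: empty histogram with the timeout flag
  h <- acquire_calibration(source_am241(0), detector_config(),
                           timeout_s = 2, min_counts = 0, seed = 3)
  expect_true(attr(h, "timeout"))
  expect_equal(sum(h$counts), 0)
  # with the default usability floor the same run is an error
  expect_error(
    acquire_calibration(source_am241(0), detector_config(),
                        timeout_s = 2, seed = 3),
    class = "scintdose_insufficient_statistics")
  expect_error(acquire_calibration(source_am241(), stop_count = 0),
               "stop_count")
})

test_that("moving-average smoothing conserves mass and handles edges", {
  expect_equal(smooth_histogram(c(3, 1, 4, 1, 5), window = 1),
               c(3, 1, 4, 1, 5))
  expect_equal(smooth_histogram(rep(7, 10), window = 5), rep(7, 10))
  # impulse of height 9, window 3 -> three bins of 3
  expect_equal(smooth_histogram(c(0, 0, 9, 0, 0), window = 3),
               c(0, 3, 3, 3, 0))
  # interior mass conservation
  x <- rpois(101, 20)
  sm <- smooth_histogram(x, window = 7)
  expect_equal(sum(sm[4:98]), sum((stats::filter(x, rep(1/7, 7)))[4:98]))
  expect_error(smooth_histogram(1:10, window = 4), "odd")
  expect_error(smooth_histogram(1:3, window = 5), "larger than histogram")
})

test_that("two clean peaks are found at their modes", {
  bins <- 0:1023
  x <- 100 * exp(-(bins - 200)^2 / (2 * 15^2)) +
       60 * exp(-(bins - 800)^2 / (2 * 25^2))
  p <- find_calibration_peaks(x, peak_mode = "argmax")
  expect_equal(p, c(200, 800))
  # centroid of a symmetric peak coincides with its mode
  pc <- find_calibration_peaks(x, peak_mode = "centroid")
  expect_equal(pc, c(200, 800), tolerance = 1e-6)
})

test_that("peak detection rejects underdetermined histograms", {
  bins <- 0:255
  one <- 50 * exp(-(bins - 100)^2 / 50)
  expect_error(find_calibration_peaks(one), "fewer than 2")
  expect_error(find_calibration_peaks(rep(0, 100)), "fewer than 2")
  # a third peak of negligible prominence is ignored
  x <- 100 * exp(-(bins - 60)^2 / 50) + 80 * exp(-(bins - 180)^2 / 50) +
       3 * exp(-(bins - 120)^2 / 50)
  expect_equal(find_calibration_peaks(x, peak_mode = "argmax"), c(60, 180))
})

test_that("peak selection agrees with brute-force prominence ranking", {
  set.seed(42)
  for (rep in 1:25) {
    x <- random_bump_histogram(64, sample(2:4, 1))
    oracle <- brute_force_peaks(x)
    got <- tryCatch(
      find_calibration_peaks(x, peak_mode = "argmax"),
      error = function(e) integer(0))
    if (length(oracle) == 2) {
      expect_equal(got, oracle, info = paste("case", rep))
    } else {
      expect_length(got, 0)
    }
  }
})

test_that("two-point fit solves the line and reproduces the anchors", {
  cal <- fit_energy_calibration(200, 800)
  expect_equal(cal$a, 40.5 / 600)
  expect_equal(cal$b, 19 - cal$a * 200)
  expect_equal(cal$b, 5.5, tolerance = 1e-12)

  cal2 <- fit_energy_calibration(190, 595)
  expect_equal(as.numeric(apply_calibration(c(190, 595), cal2)),
               c(19, 59.5), tolerance = 1e-12)
  expect_error(fit_energy_calibration(500, 500), "degenerate")
})

test_that("valid range is the ADC span clipped to table coverage", {
  cal <- fit_energy_calibration(190, 595, n_bins = 1024)
  cov <- table_coverage(tabs)
  expect_equal(cal$valid_range[1], max(cal$b, cov[1]))
  expect_equal(cal$valid_range[2], min(cal$a * 1023 + cal$b, cov[2]))
  e <- apply_calibration(c(0, 500, 1023), cal)
  expect_identical(attr(e, "in_range"),
                   e >= cal$valid_range[1] & e <= cal$valid_range[2])
  ident <- fit_energy_calibration(19, 59.5, n_bins = 1024)  # a = 1, b = 0
  expect_equal(as.numeric(apply_calibration(0:5, ident)), 0:5 * 1 + 0)
})

test_that("noiseless round-trip recovers the inverse gain within half a bin", {
  two_line <- source_am241(2e4, line_energies = c(19, 59.5),
                           line_weights = c(0.6, 0.4))
  for (gain_a in c(5, 10, 20)) {
    for (gain_b in c(-20, 0, 20)) {
      # 2048 bins so the 59.5 keV line stays in range at the highest gain
      cfg <- detector_config(gain_a = gain_a, gain_b = gain_b,
                             resolution_sigma = 0, threshold = 0,
                             n_bins = 2048)
      s <- detect_and_digitize(two_line, NULL, cfg, 1,
                               attenuation_table = NULL, seed = 11)
      cal <- calibrate_histogram(build_histogram(s), window = 1,
                                 min_prominence = 0.05)
      # the fitted map sends the exact (unrounded) anchor amplitudes back to
      # the anchor energies within half-bin quantization
      for (E in c(19, 59.5)) {
        amp <- gain_a * E + gain_b
        expect_lt(abs(cal$a * amp + cal$b - E), 0.5 * cal$a + 1e-9)
      }
    }
  }
})

test_that("seeded Am-241 auto-calibration approximates the inverse gain", {
  cfg <- detector_config()
  h <- acquire_calibration(source_am241(2e4), cfg, seed = 17)
  cal <- calibrate_histogram(h)
  expect_equal(as.numeric(apply_calibration(cal$peak_bins, cal)),
               c(19, 59.5), tolerance = 1e-9)   # anchors by construction
  expect_lt(abs(cal$a - 1 / cfg$gain_a) / (1 / cfg$gain_a), 0.15)
  expect_true(cal$peak_bins[1] < cal$peak_bins[2])
})

test_that("calibrations persist through JSON", {
  cal <- fit_energy_calibration(212.4, 781.9)
  p <- tempfile(fileext = ".json")
  save_calibration(cal, p)
  r <- load_calibration(p)
  expect_equal(r$a, cal$a)
  expect_equal(r$b, cal$b)
  expect_equal(r$valid_range, cal$valid_range)
  expect_equal(as.numeric(r$peak_bins), as.numeric(cal$peak_bins))
})
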