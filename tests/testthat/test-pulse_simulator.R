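test_that("source sampling honors the spectral model", {
  expect_equal(sample_source(source_monoenergetic(60), 5), rep(60, 5))

  # Am-241: the sub-30 keV envelope's histogram mode lies in 10-23 keV
  e <- sample_source(source_am241(), 1e5, seed = 1)
  low <- e[e < 30]
  mode_keV <- as.numeric(names(which.max(table(low))))
  expect_gte(mode_keV, 10)
  expect_lte(mode_keV, 23)
  # and the 59.5 keV gamma line is present
  expect_gt(mean(e > 55), 0.3)

  expect_error(sample_source(list(kind = "mystery"), 10), "unknown source")
  expect_error(source_am241(line_weights = c(-1, 2)), "lengths differ")
  expect_error(new_source <- source_monoenergetic(-5), "positive")
})

test_that("tube spectra are bounded by kVp and harden with Pb filtration", {
  src2 <- source_tube(120, 2)
  src8 <- source_tube(120, 8)
  e2 <- sample_source(src2, 2e4, seed = 2)
  expect_true(all(e2 <= 120))
  # sample mean agrees with the model's analytic mean within 3 sigma
  mu_analytic <- sum(src2$weights * src2$energies)
  sd_line <- sqrt(sum(src2$weights * (src2$energies - mu_analytic)^2))
  expect_lt(abs(mean(e2) - mu_analytic), 3 * sd_line / sqrt(length(e2)))
  # more filtration -> harder beam
  mu8 <- sum(src8$weights * src8$energies)
  expect_gt(mu8, mu_analytic)
  # mm-scale Pb filtration concentrates the beam just below the Pb K-edge
  expect_true(mu_analytic > 75 && mu_analytic < 88)
})

test_that("noiseless digitization reproduces the affine gain exactly", {
  cfg <- detector_config(gain_a = 10, gain_b = 10, resolution_sigma = 0,
                         threshold = 0)
  s <- detect_and_digitize(source_monoenergetic(60), 1000, cfg, 1,
                           attenuation_table = NULL, seed = 3)
  expect_true(all(s$adc == round(10 * 60 + 10)))
  expect_equal(s$true_keV, rep(60, length(s$adc)))
})

test_that("pulse accounting and reproducibility invariants hold", {
  cfg <- detector_config()
  for (seed in 1:3) {
    s <- detect_and_digitize(source_am241(5e4), NULL, cfg, 1, seed = seed)
    expect_identical(length(s$adc) + s$dropped_count + s$subthreshold_count,
                     s$absorbed_count)
    expect_true(!is.unsorted(s$timestamps))
    expect_true(all(s$adc >= 0 & s$adc < cfg$n_bins))
  }
  a <- detect_and_digitize(source_am241(1e4), NULL, cfg, 1, seed = 9)
  b <- detect_and_digitize(source_am241(1e4), NULL, cfg, 1, seed = 9)
  expect_identical(a, b)
})

test_that("absorption thinning matches eta within 3 sigma (deadtime off)", {
  cfg <- detector_config(threshold = 0, tau = 1e-9)
  rate <- 2e4
  s <- detect_and_digitize(source_monoenergetic(60, rate), NULL, cfg, 2,
                           seed = 4)
  expected <- absorption_efficiency(60, cfg$geometry) * rate * 2
  expect_lt(abs(length(s$adc) - expected), 3 * sqrt(expected))
})

test_that("accepted rate follows the non-paralyzable closed form", {
  cfg <- detector_config(threshold = 0)
  rate <- 1e5
  dur <- 2
  s <- detect_and_digitize(source_monoenergetic(60, rate), NULL, cfg, dur,
                           attenuation_table = NULL, seed = 5)
  expected <- observed_rate(rate, cfg$tau) * dur
  expect_lt(abs(length(s$adc) - expected), 3 * sqrt(expected))
})

test_that("amplitude saturation clamps at the last bin", {
  cfg <- detector_config(gain_a = 10, gain_b = 0, resolution_sigma = 0,
                         threshold = 0)
  s <- detect_and_digitize(source_monoenergetic(150), 500, cfg, 1,
                           attenuation_table = NULL, seed = 6)
  expect_true(all(s$adc == cfg$n_bins - 1L))
})

test_that("pile-up sums coincident amplitudes instead of dropping them", {
  noise_free <- detector_config(gain_a = 10, gain_b = 0,
                                resolution_sigma = 0, threshold = 0)
  pile_cfg <- detector_config(gain_a = 10, gain_b = 0, resolution_sigma = 0,
                              threshold = 0, pileup_enabled = TRUE)
  rate <- 2e5  # rate * tau = 2.6: heavy coincidence
  s0 <- detect_and_digitize(source_monoenergetic(30, rate), NULL,
                            noise_free, 0.5, attenuation_table = NULL,
                            seed = 7)
  s1 <- detect_and_digitize(source_monoenergetic(30, rate), NULL,
                            pile_cfg, 0.5, attenuation_table = NULL,
                            seed = 7)
  expect_true(all(s0$adc == 300))
  expect_gt(mean(s1$adc), 350)       # summed amplitudes shift the mean up
  expect_identical(s0$dropped_count, s1$dropped_count)  # same train
})

test_that("degenerate inputs are rejected or yield empty streams", {
  cfg <- detector_config()
  expect_error(detect_and_digitize(source_am241(), NULL, cfg, 0), "duration")
  expect_error(detect_and_digitize(numeric(0), 100, cfg, 1),
               "unknown source")
  s <- detect_and_digitize(source_am241(0), NULL, cfg, 1, seed = 8)
  expect_length(s$adc, 0)
  expect_s3_class(s, "pulse_stream")
})

test_that("pulse streams round-trip through CSV", {
  cfg <- detector_config()
  s <- detect_and_digitize(source_am241(5e3), NULL, cfg, 1, seed = 10)
  p <- tempfile(fileext = ".csv")
  write_pulse_stream(s, p)
  r <- read_pulse_stream(p, duration = s$duration, config = cfg)
  expect_equal(r$timestamps, s$timestamps)
  expect_identical(r$adc, s$adc)
  expect_equal(r$true_keV, s$true_keV)
})
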