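# Reference transition graph of the single-button interface, stated
# independently of the implementation: screens x events -> screens.
oracle_transition <- function(screen, event) {
  if (event == "short_press") {
    switch(screen, dose_rate = "accumulated", accumulated = "dose_rate",
           options = "dose_rate", calibrating = "calibrating")
  } else if (event == "long_press") {
    switch(screen, dose_rate = "options", accumulated = "options",
           options = "calibrating", calibrating = "calibrating")
  } else {
    switch(screen, calibrating = "dose_rate", screen)
  }
}

test_that("state machine matches the reference graph under exhaustive walks", {
  events <- c("short_press", "long_press", "tick")
  for (len in 1:6) {
    seqs <- do.call(expand.grid, c(rep(list(events), len),
                                   stringsAsFactors = FALSE))
    for (r in seq_len(nrow(seqs))) {
      st <- device_state()
      screen <- "dose_rate"
      for (ev in unlist(seqs[r, ])) {
        st <- step_state(st, ev)
        screen <- oracle_transition(screen, ev)
      }
      expect_identical(st$screen, screen)
    }
  }
})

test_that("display screens cycle with period two and options resets dose", {
  st <- device_state()
  st <- step_state(st, "tick", increment_Sv = 2e-6)
  expect_equal(st$dose$accumulated_Sv, 2e-6)
  # 4 short presses return to the dose-rate screen (cycle of 2)
  for (i in 1:4) st <- step_state(st, "short_press")
  expect_identical(st$screen, "dose_rate")
  # long press -> options; short press resets the dose values
  st <- step_state(st, "long_press")
  expect_identical(st$screen, "options")
  st <- step_state(st, "short_press")
  expect_equal(st$dose$accumulated_Sv, 0)
  expect_identical(st$screen, "dose_rate")
  # calibration is reachable only through options and survives a reset
  cal <- fit_energy_calibration(190, 595)
  st2 <- device_state(calibration = cal)
  st2 <- step_state(step_state(st2, "long_press"), "short_press")
  expect_false(is.null(st2$calibration))
})

test_that("the dose log is a strict ring buffer", {
  log <- dose_log(retention_hours = 5 / 3600)  # capacity 5, fast to fill
  expect_equal(log$capacity, 5L)
  for (t in 1:5) log_sample(log, t, t * 1.0, t * 2.0)
  expect_equal(log_length(log), 5L)
  log_sample(log, 6, 6, 12)
  expect_equal(log_length(log), 5L)            # oldest evicted
  df <- log_entries(log)
  expect_equal(df$t_s, 2:6)                    # first entry gone
  expect_equal(df$dose_rate_uSv_h, 2:6 * 1.0)
  expect_true(all(diff(df$t_s) > 0))
  expect_error(log_sample(log, 6, 0, 0), "non-monotone")
  expect_error(dose_log(0), "positive")
})

test_that("log export round-trips losslessly and handles empty logs", {
  log <- dose_log(retention_hours = 1 / 360)   # capacity 10
  p <- tempfile(fileext = ".csv")
  export_log(log, p)
  empty <- read_dose_log(p)
  expect_equal(nrow(empty), 0)                 # header-only CSV
  expect_named(empty, c("t_s", "dose_rate_uSv_h", "accumulated_uSv",
                        "deadtime_fraction", "discarded_counts"))

  set.seed(1)
  for (t in 1:3) {
    log_sample(log, t, runif(1) * 17, runif(1) * 3, runif(1), rpois(1, 2))
  }
  export_log(log, p)
  expect_equal(length(readLines(p)), 4L)       # header + 3 rows
  back <- read_dose_log(p)
  expect_identical(back, log_entries(log))     # bit-exact round trip
})

test_that("the device loop accumulates the same dose as a single histogram", {
  cfg <- detector_config()
  cal <- exact_calibration(cfg)
  stream <- detect_and_digitize(source_am241(5e3), NULL, cfg, 5, seed = 21)
  st <- device_run(stream, cal)
  expect_equal(log_length(st$log), 5L)
  df <- log_entries(st$log)
  expect_true(all(diff(df$accumulated_uSv) >= 0))
  # windowed accumulation agrees with the whole-stream dose within the
  # (tiny) per-window deadtime-correction differences
  whole <- spectrum_dose(build_histogram(stream, cfg), cal)
  expect_equal(st$dose$accumulated_Sv, as.numeric(whole), tolerance = 1e-3)
})
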