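#' Bounded 1 Hz dose log (ring buffer)
#'
#' The device logs one sample per second and retains the most recent
#' `retention_hours` of samples; with the defaults (10 h at 1 Hz) the
#' capacity is 36,000 entries. When full, each append evicts the single
#' oldest entry. Implemented as a preallocated ring buffer in an
#' environment, so appends are O(1) and the log object has reference
#' semantics (functions return it invisibly for convenience).
#'
#' @param retention_hours retention span in hours (default 10).
#' @param rate_hz sampling rate in Hz (default 1).
#' @return object of class `dose_log`.
#' @export
dose_log <- function(retention_hours = 10, rate_hz = 1) {
  if (retention_hours <= 0 || rate_hz <= 0) {
    stop("retention_hours and rate_hz must be positive")
  }
  capacity <- as.integer(round(retention_hours * 3600 * rate_hz))
  log <- new.env(parent = emptyenv())
  log$capacity <- capacity
  log$rate_hz <- rate_hz
  log$t_s <- numeric(capacity)
  log$dose_rate_uSv_h <- numeric(capacity)
  log$accumulated_uSv <- numeric(capacity)
  log$deadtime_fraction <- numeric(capacity)
  log$discarded_counts <- numeric(capacity)
  log$n <- 0L        # entries currently held
  log$head <- 0L     # slot of the most recent entry (1-based; 0 = empty)
  class(log) <- "dose_log"
  log
}

#' Append a sample to the dose log
#'
#' Timestamps must be strictly increasing; when the buffer is full the
#' oldest entry is evicted.
#'
#' @param log a [dose_log()].
#' @param t_s sample timestamp in seconds.
#' @param dose_rate_uSv_h instantaneous dose rate, uSv/h.
#' @param accumulated_uSv accumulated dose, uSv.
#' @param deadtime_fraction,discarded_counts per-window diagnostics.
#' @return the log, invisibly.
#' @export
log_sample <- function(log, t_s, dose_rate_uSv_h, accumulated_uSv,
                       deadtime_fraction = 0, discarded_counts = 0) {
  stopifnot(inherits(log, "dose_log"))
  if (log$n > 0L) {
    last <- log$t_s[log$head]
    if (t_s <= last) {
      stop(sprintf("non-monotone timestamp: %g <= last logged %g", t_s, last))
    }
  }
  slot <- (log$head %% log$capacity) + 1L
  log$t_s[slot] <- t_s
  log$dose_rate_uSv_h[slot] <- dose_rate_uSv_h
  log$accumulated_uSv[slot] <- accumulated_uSv
  log$deadtime_fraction[slot] <- deadtime_fraction
  log$discarded_counts[slot] <- discarded_counts
  log$head <- slot
  if (log$n < log$capacity) log$n <- log$n + 1L
  invisible(log)
}

#' @rdname log_sample
#' @export
log_length <- function(log) {
  stopifnot(inherits(log, "dose_log"))
  log$n
}

#' Dose log contents in chronological order
#'
#' @param log a [dose_log()].
#' @return data frame with columns `t_s`, `dose_rate_uSv_h`,
#'   `accumulated_uSv`, `deadtime_fraction`, `discarded_counts`.
#' @export
log_entries <- function(log) {
  stopifnot(inherits(log, "dose_log"))
  if (log$n == 0L) {
    return(data.frame(t_s = numeric(0), dose_rate_uSv_h = numeric(0),
                      accumulated_uSv = numeric(0),
                      deadtime_fraction = numeric(0),
                      discarded_counts = numeric(0)))
  }
  idx <- if (log$n < log$capacity) seq_len(log$n)
         else ((log$head + seq_len(log$capacity) - 1L) %% log$capacity) + 1L
  data.frame(t_s = log$t_s[idx],
             dose_rate_uSv_h = log$dose_rate_uSv_h[idx],
             accumulated_uSv = log$accumulated_uSv[idx],
             deadtime_fraction = log$deadtime_fraction[idx],
             discarded_counts = log$discarded_counts[idx])
}

#' @export
print.dose_log <- function(x, ...) {
  cat(sprintf("<dose_log: %d / %d samples at %g Hz>\n",
              x$n, x$capacity, x$rate_hz))
  invisible(x)
}

#' Export / read the dose log as CSV
#'
#' Writes the chronological log as
#' `t_s,dose_rate_uSv_h,accumulated_uSv,deadtime_fraction,discarded_counts`;
#' an empty log yields a header-only file. The write/read pair round-trips
#' all rows losslessly.
#'
#' @param log a [dose_log()].
#' @param path CSV file path.
#' @return `read_dose_log` returns the log data frame.
#' @export
export_log <- function(log, path) {
  df <- log_entries(log)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df)) {
    writeLines(do.call(sprintf, c(list("%.17g,%.17g,%.17g,%.17g,%.17g"),
                                  df)), con)
  }
  invisible(path)
}

#' @rdname export_log
#' @export
read_dose_log <- function(path) {
  df <- read.csv(path)
  need <- c("t_s", "dose_rate_uSv_h", "accumulated_uSv",
            "deadtime_fraction", "discarded_counts")
  if (!all(need %in% names(df))) {
    stop("dose log CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df <- df[need]
  df[] <- lapply(df, as.numeric)
  df
}

#' Device state and single-button state machine
#'
#' Software emulation of the device's user interface: two display screens
#' (`dose_rate`, `accumulated`) cycled by short presses; a long press opens
#' `options`, where a short press resets the dose values (calibration is
#' kept — on the physical device it survives power cycling) and a long
#' press starts `calibrating`. A `tick` event is the 1 Hz loop: in display
#' screens and options it accumulates the window's dose increment and logs a
#' sample; in `calibrating` it completes the procedure and returns to the
#' dose-rate screen.
#'
#' @param calibration an `energy_calibration` or `NULL` (uncalibrated).
#' @param retention_hours,rate_hz log configuration.
#' @return object of class `device_state` with fields `screen`, `dose`,
#'   `calibration`, `log`.
#' @export
device_state <- function(calibration = NULL, retention_hours = 10,
                         rate_hz = 1) {
  structure(list(screen = "dose_rate",
                 dose = dose_state(window_s = 1 / rate_hz),
                 calibration = calibration,
                 log = dose_log(retention_hours, rate_hz)),
            class = "device_state")
}

#' @rdname device_state
#' @param state a `device_state`.
#' @param event `"short_press"`, `"long_press"`, or `"tick"`.
#' @param increment_Sv dose increment for a `tick` event, Sv.
#' @param deadtime_fraction,discarded_counts diagnostics logged with a tick.
#' @export
step_state <- function(state, event = c("short_press", "long_press", "tick"),
                       increment_Sv = 0, deadtime_fraction = 0,
                       discarded_counts = 0) {
  stopifnot(inherits(state, "device_state"))
  event <- match.arg(event)
  screen <- state$screen
  if (event == "short_press") {
    state$screen <- switch(screen,
      dose_rate = "accumulated",
      accumulated = "dose_rate",
      options = { state$dose <- reset_dose(state$dose); "dose_rate" },
      calibrating = "calibrating")   # no-op while calibrating
  } else if (event == "long_press") {
    state$screen <- switch(screen,
      dose_rate = "options",
      accumulated = "options",
      options = "calibrating",
      calibrating = "calibrating")   # no-op while calibrating
  } else {                           # tick: the 1 Hz loop
    if (screen == "calibrating") {
      state$screen <- "dose_rate"    # calibration procedure completes
    } else {
      state$dose <- accumulate(state$dose, increment_Sv)
      log_sample(state$log, state$dose$time_s,
                 state$dose$last_rate_Sv_h * 1e6,
                 state$dose$accumulated_Sv * 1e6,
                 deadtime_fraction, discarded_counts)
    }
  }
  state
}

#' Run the 1 Hz device loop over a pulse stream
#'
#' Slices a pulse stream into consecutive windows, converts each window's
#' histogram to a dose increment through the full pipeline, and advances a
#' device state (accumulating and logging at the device rate). This is the
#' software stand-in for wearing the device.
#'
#' @param stream a `pulse_stream`.
#' @param calibration an `energy_calibration`.
#' @param tables,geometry physics inputs, as in [spectrum_dose()].
#' @param state optional existing `device_state` to continue.
#' @param window_s window length in seconds (default 1).
#' @return the final `device_state`; its `log` holds one sample per window.
#' @export
device_run <- function(stream, calibration, tables = scintdose_tables(),
                       geometry = detector_geometry(), state = NULL,
                       window_s = 1) {
  stopifnot(inherits(stream, "pulse_stream"))
  if (is.null(state)) {
    state <- device_state(calibration, rate_hz = 1 / window_s)
  }
  n_win <- max(1L, floor(stream$duration / window_s))
  cfg <- stream$config
  for (w in seq_len(n_win)) {
    sel <- stream$timestamps > (w - 1) * window_s &
      stream$timestamps <= w * window_s
    counts <- tabulate(stream$adc[sel] + 1L, nbins = cfg$n_bins)
    h <- pulse_histogram(counts, window_s, cfg$tau)
    inc <- spectrum_dose(h, calibration, tables, geometry)
    state <- step_state(state, "tick", increment_Sv = as.numeric(inc),
                        deadtime_fraction = attr(inc, "deadtime_fraction"),
                        discarded_counts = attr(inc, "discarded_counts"))
  }
  state
}
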