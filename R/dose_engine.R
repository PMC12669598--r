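#' Spectrum-to-dose conversion
#'
#' One time window's calibrated, deadtime-corrected pulse-height spectrum is
#' converted to an effective-dose increment by inverting the detector
#' response bin by bin: corrected counts are divided by the absorption
#' efficiency `eta(E)` (recovering the incident photon number) and
#' multiplied by the per-photon dose `e(E)/A`. Bin energies are evaluated at
#' bin centers through the calibration map. Bins mapping outside the
#' calibration's valid range or the tables' coverage, or with
#' `eta < efficiency_floor`, are excluded from the sum and tallied in a
#' discard counter — dividing by a near-zero efficiency would explosively
#' amplify noise counts.
#'
#' @param histogram a [pulse_histogram()] for the window.
#' @param calibration an `energy_calibration`; omitting it is an error (the
#'   device must be calibrated first).
#' @param tables physics tables from [load_tables()].
#' @param geometry a [detector_geometry()].
#' @param efficiency_floor minimum `eta(E)` for a bin to enter the sum
#'   (default 0.01).
#' @param correct_deadtime apply the `1/(1 - deadtime_fraction)` count
#'   correction first (default `TRUE`).
#' @param cap deadtime reliability cap passed to [correct_counts()].
#' @return dose increment for the window in Sv (scalar), with attributes
#'   `discarded_counts` (raw counts excluded) and `deadtime_fraction`.
#' @examples
#' cal <- fit_energy_calibration(190, 595)
#' h <- pulse_histogram(tabulate(rep(595, 100), 1024), real_time = 1)
#' spectrum_dose(h, cal)
#' @export
spectrum_dose <- function(histogram, calibration,
                          tables = scintdose_tables(),
                          geometry = detector_geometry(),
                          efficiency_floor = 0.01,
                          correct_deadtime = TRUE, cap = 0.9) {
  stopifnot(inherits(histogram, "pulse_histogram"))
  if (missing(calibration) || is.null(calibration)) {
    stop("device must be calibrated first: no energy calibration supplied")
  }
  stopifnot(inherits(calibration, "energy_calibration"))

  counts <- if (correct_deadtime) correct_counts(histogram, cap = cap)
            else histogram$counts
  bins <- seq_len(histogram$n_bins) - 1
  energy <- apply_calibration(bins, calibration)
  cov <- table_coverage(tables)
  ok <- attr(energy, "in_range") & energy >= cov[1] & energy <= cov[2]
  eta <- rep(NA_real_, length(bins))
  eta[ok] <- absorption_efficiency(energy[ok], geometry, tables$attenuation)
  ok[ok] <- eta[ok] >= efficiency_floor

  dose_pSv <- if (any(ok)) {
    pd <- per_photon_dose(energy[ok], geometry, tables$dose)
    sum(counts[ok] / eta[ok] * pd)
  } else 0
  structure(dose_pSv * 1e-12,
            discarded_counts = sum(histogram$counts[!ok]),
            deadtime_fraction = histogram$deadtime_fraction)
}

#' Dose rate from a window increment
#'
#' @param increment_Sv dose increment in Sv.
#' @param window_s window length in seconds (> 0).
#' @return dose rate in Sv/h (`increment / window * 3600`).
#' @examples
#' dose_rate(1e-9, 1)  # 1 nSv over 1 s = 3.6e-6 Sv/h
#' @export
dose_rate <- function(increment_Sv, window_s) {
  if (any(window_s <= 0)) stop("window_s must be positive")
  increment_Sv / window_s * 3600
}

#' Running dose state
#'
#' Accumulated dose and last dose rate, advanced one window at a time.
#' Accumulated dose is non-negative and non-decreasing until an explicit
#' [reset_dose()].
#'
#' @param window_s update window in seconds (default 1, the 1 Hz device
#'   loop).
#' @return object of class `dose_state` with fields `accumulated_Sv`,
#'   `last_rate_Sv_h`, `window_s`, `time_s`.
#' @export
dose_state <- function(window_s = 1) {
  if (window_s <= 0) stop("window_s must be positive")
  structure(list(accumulated_Sv = 0, last_rate_Sv_h = 0,
                 window_s = window_s, time_s = 0),
            class = "dose_state")
}

#' Accumulate one window's dose increment
#'
#' @param state a [dose_state()].
#' @param increment_Sv non-negative dose increment in Sv for one window.
#' @return the updated `dose_state` (accumulated dose increased, last rate
#'   and elapsed time updated).
#' @export
accumulate <- function(state, increment_Sv) {
  stopifnot(inherits(state, "dose_state"))
  increment_Sv <- as.numeric(increment_Sv)
  if (!is.finite(increment_Sv) || increment_Sv < 0) {
    stop("increment_Sv must be a non-negative finite number")
  }
  state$accumulated_Sv <- state$accumulated_Sv + increment_Sv
  state$last_rate_Sv_h <- dose_rate(increment_Sv, state$window_s)
  state$time_s <- state$time_s + state$window_s
  state
}

#' @rdname accumulate
#' @export
reset_dose <- function(state) {
  stopifnot(inherits(state, "dose_state"))
  state$accumulated_Sv <- 0
  state$last_rate_Sv_h <- 0
  state
}

#' @export
print.dose_state <- function(x, ...) {
  cat(sprintf(paste0("<dose_state: accumulated %.4g uSv, last rate %.4g ",
                     "uSv/h, t = %g s>\n"),
              x$accumulated_Sv * 1e6, x$last_rate_Sv_h * 1e6, x$time_s))
  invisible(x)
}
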