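#' Pulse-height histogram with acquisition metadata
#'
#' Counts per ADC bin (bins `0 .. n_bins-1`) plus the real (wall-clock)
#' acquisition time, the observed count rate, and the estimated deadtime
#' fraction `observed_rate * tau` — the quantity the firmware computes by
#' multiplying the output count rate by the average per-pulse sampling time.
#'
#' @param counts non-negative integer counts per bin.
#' @param real_time acquisition real time in seconds (> 0).
#' @param tau per-pulse sampling time in seconds.
#' @return object of class `pulse_histogram` with fields `counts`, `n_bins`,
#'   `real_time`, `observed_rate`, `deadtime_fraction`.
#' @export
pulse_histogram <- function(counts, real_time, tau = 13e-6) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (real_time <= 0) stop("real_time must be positive")
  rate <- sum(counts) / real_time
  structure(list(counts = as.numeric(counts), n_bins = length(counts),
                 real_time = real_time, observed_rate = rate,
                 deadtime_fraction = deadtime_fraction(rate, tau),
                 tau = tau),
            class = "pulse_histogram")
}

#' Build a pulse-height histogram from a pulse stream
#'
#' Bins every accepted pulse of the stream; counts are conserved
#' (`sum(counts) == length(stream$adc)`). An empty stream yields a valid
#' all-zero histogram.
#'
#' @param stream a `pulse_stream`.
#' @param config a [detector_config()]; defaults to the stream's own config.
#' @return a [pulse_histogram()].
#' @export
build_histogram <- function(stream, config = stream$config) {
  stopifnot(inherits(stream, "pulse_stream"))
  if (length(stream$adc) && (min(stream$adc) < 0 ||
                             max(stream$adc) >= config$n_bins)) {
    stop("stream adc values outside [0, n_bins)")
  }
  counts <- tabulate(stream$adc + 1L, nbins = config$n_bins)
  pulse_histogram(counts, stream$duration, config$tau)
}

#' @export
print.pulse_histogram <- function(x, ...) {
  cat(sprintf(paste0("<pulse_histogram: %d bins, %d counts, %.3g s, ",
                     "%.4g cps, deadtime %.2f%%>\n"),
              x$n_bins, round(sum(x$counts)), x$real_time, x$observed_rate,
              100 * x$deadtime_fraction))
  invisible(x)
}

#' Non-paralyzable observed count rate
#'
#' Closed-form output rate of a non-paralyzable counter,
#' `n_out = n_in / (1 + n_in * tau)`: strictly increasing in the input rate
#' and saturating at `1/tau` (about 77 kcps for `tau = 13e-6`).
#'
#' @param true_rate input (triggered-pulse) rate, per second, >= 0;
#'   vectorized. `Inf` is allowed and returns the asymptote `1/tau`.
#' @param tau deadtime per accepted pulse, seconds (> 0).
#' @return observed rate, per second.
#' @examples
#' observed_rate(1e5, 13e-6)  # 1e5 / 2.3
#' @export
observed_rate <- function(true_rate, tau = 13e-6) {
  if (any(true_rate < 0, na.rm = TRUE)) stop("true_rate must be >= 0")
  if (tau <= 0) stop("tau must be positive")
  ifelse(is.infinite(true_rate), 1 / tau, true_rate / (1 + true_rate * tau))
}

#' Deadtime fraction from the observed rate
#'
#' The firmware's deadtime estimate: `observed * tau`, the fraction of real
#' time the pulse processor is busy. Physically observable rates satisfy
#' `observed * tau < 1`; anything at or beyond saturation raises an error.
#'
#' @param observed observed count rate, per second, >= 0; vectorized.
#' @param tau deadtime per accepted pulse, seconds (> 0).
#' @return fraction in `[0, 1)`.
#' @export
deadtime_fraction <- function(observed, tau = 13e-6) {
  if (any(observed < 0, na.rm = TRUE)) stop("observed rate must be >= 0")
  if (tau <= 0) stop("tau must be positive")
  f <- observed * tau
  if (any(f >= 1, na.rm = TRUE)) {
    stop("observed rate at or beyond saturation (observed * tau >= 1): ",
         "not physically observable")
  }
  f
}

#' Deadtime-correct histogram counts
#'
#' Scales every bin by `1 / (1 - deadtime_fraction)`, the algebraic inverse
#' of the non-paralyzable rate loss: applied to the observed rate
#' `m/(1 + m tau)` it recovers the true rate `m` exactly. Corrected counts
#' are real-valued (not re-rounded) to avoid bias in dose sums. Beyond the
#' guard cap the device's own output is declared unreliable and the
#' correction refuses to run.
#'
#' @param histogram a [pulse_histogram()], or a bare numeric vector of
#'   counts (then `deadtime` must be given).
#' @param tau deadtime per accepted pulse, seconds.
#' @param cap guard cap on the deadtime fraction (default 0.9, i.e. a
#'   maximum correction factor of 10).
#' @param deadtime deadtime fraction override when `histogram` is a bare
#'   vector.
#' @return numeric vector of corrected (real-valued) counts per bin.
#' @export
correct_counts <- function(histogram, tau = NULL, cap = 0.9,
                           deadtime = NULL) {
  if (inherits(histogram, "pulse_histogram")) {
    counts <- histogram$counts
    if (is.null(deadtime)) {
      deadtime <- if (is.null(tau)) histogram$deadtime_fraction
                  else deadtime_fraction(histogram$observed_rate, tau)
    }
  } else {
    counts <- histogram
    if (is.null(deadtime)) stop("deadtime fraction required for bare counts")
  }
  if (deadtime < 0 || deadtime >= 1) stop("deadtime fraction must be in [0, 1)")
  if (deadtime >= cap) {
    stop(sprintf(paste0("deadtime fraction %.3f exceeds the reliability cap ",
                        "%.2f: output rate unreliable, refusing to correct"),
                 deadtime, cap))
  }
  counts / (1 - deadtime)
}

#' Read / write histograms as CSV
#'
#' Histograms are stored as `bin,counts` CSV with `#` metadata lines
#' carrying `real_time`, `observed_rate`, `deadtime_fraction`, and `tau`.
#'
#' @param histogram a [pulse_histogram()].
#' @param path file path.
#' @return `read_histogram` returns a [pulse_histogram()].
#' @export
write_histogram <- function(histogram, path) {
  stopifnot(inherits(histogram, "pulse_histogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# real_time: %.17g", histogram$real_time),
    sprintf("# observed_rate: %.17g", histogram$observed_rate),
    sprintf("# deadtime_fraction: %.17g", histogram$deadtime_fraction),
    sprintf("# tau: %.17g", histogram$tau),
    "bin,counts"), con)
  writeLines(sprintf("%d,%.17g", seq_len(histogram$n_bins) - 1L,
                     histogram$counts), con)
  invisible(path)
}

#' @rdname write_histogram
#' @export
read_histogram <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key, default = NA_real_) {
    hit <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (!length(hit)) return(default)
    as.numeric(sub(paste0("^# ", key, ":\\s*"), "", hit[1]))
  }
  df <- read.csv(text = lines[!startsWith(lines, "#")])
  if (!all(c("bin", "counts") %in% names(df))) {
    stop("histogram CSV needs columns bin and counts")
  }
  counts <- numeric(max(df$bin) + 1L)
  counts[df$bin + 1L] <- df$counts
  pulse_histogram(counts, get_meta("real_time", 1),
                  tau = get_meta("tau", 13e-6))
}
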