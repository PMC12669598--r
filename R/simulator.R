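#' Detector / digitizer configuration
#'
#' Parameters of the simulated pulse chain: affine ADC gain
#' (`adc = gain_a * E + gain_b`), Gaussian pulse-height resolution, trigger
#' threshold, histogram depth, and the non-paralyzable per-pulse sampling
#' (dead) time `tau`.
#'
#' The resolution model follows scintillation counting statistics: the
#' amplitude sigma scales with the square root of the amplitude,
#' `sigma(A) = resolution_sigma * sqrt(A / A_ref)`, where `A_ref` is the
#' amplitude of the 59.5 keV reference line under the configured gain. With
#' `resolution_scaling = "constant"` the sigma is amplitude-independent.
#' The default `resolution_sigma = 60` bins at `gain_a = 10` corresponds to
#' about 23% FWHM at 59.5 keV, typical for a small LYSO + SiPM detector.
#'
#' @param geometry a [detector_geometry()].
#' @param gain_a ADC bins per keV (> 0); default 10.
#' @param gain_b ADC bin offset; default 10.
#' @param resolution_sigma amplitude sigma in ADC bins at the 59.5 keV
#'   reference amplitude (0 disables noise).
#' @param resolution_scaling `"sqrt"` (default) or `"constant"`.
#' @param threshold trigger threshold in ADC bins; pulses at or below it do
#'   not trigger sampling. Must satisfy `0 <= threshold < n_bins`.
#' @param n_bins histogram length (default 1024).
#' @param tau average per-pulse sampling time in seconds (default 13e-6).
#' @param pileup_enabled if `TRUE`, pulses arriving inside the dead window
#'   are amplitude-summed into the pending pulse instead of being lost.
#' @return object of class `detector_config`.
#' @export
detector_config <- function(geometry = detector_geometry(),
                            gain_a = 10, gain_b = 10,
                            resolution_sigma = 60,
                            resolution_scaling = c("sqrt", "constant"),
                            threshold = 50, n_bins = 1024,
                            tau = 13e-6, pileup_enabled = FALSE) {
  resolution_scaling <- match.arg(resolution_scaling)
  stopifnot(inherits(geometry, "detector_geometry"))
  if (gain_a <= 0) stop("gain_a must be positive")
  if (threshold < 0 || threshold >= n_bins) {
    stop("threshold must satisfy 0 <= threshold < n_bins")
  }
  if (tau <= 0) stop("tau must be positive")
  if (resolution_sigma < 0) stop("resolution_sigma must be non-negative")
  if (n_bins < 2) stop("n_bins must be at least 2")
  structure(list(geometry = geometry, gain_a = gain_a, gain_b = gain_b,
                 resolution_sigma = resolution_sigma,
                 resolution_scaling = resolution_scaling,
                 threshold = threshold, n_bins = as.integer(n_bins),
                 tau = tau, pileup_enabled = isTRUE(pileup_enabled)),
            class = "detector_config")
}

# sigma of the analog amplitude for an expected (noise-free) amplitude a0
amplitude_sigma <- function(config, a0) {
  if (config$resolution_sigma == 0) return(rep(0, length(a0)))
  if (config$resolution_scaling == "constant") {
    return(rep(config$resolution_sigma, length(a0)))
  }
  a_ref <- config$gain_a * 59.5 + config$gain_b
  config$resolution_sigma * sqrt(pmax(a0, 0) / a_ref)
}

#' Simulate detection and digitization of a photon stream
#'
#' Full Monte-Carlo model of the pulse chain for one acquisition:
#' Poisson arrivals at `arrival_rate` over `duration`; photon energies drawn
#' from `source` (a `source_model`, or a numeric vector treated as an
#' empirical spectrum to resample); absorption thinning with probability
#' `eta(E)` (skipped when `attenuation_table` is `NULL`, i.e. `eta = 1`);
#' analog amplitude `gain_a * E + gain_b` plus Gaussian noise; comparator
#' threshold (sub-threshold pulses neither register nor open a dead window);
#' non-paralyzable deadtime of `tau` seconds per accepted pulse, with
#' optional amplitude pile-up; digitization by rounding, clamping at the last
#' bin (pulse-height saturation).
#'
#' @param source a `source_model`, or a numeric vector of energies (keV)
#'   resampled with replacement.
#' @param arrival_rate photons per second incident on the detector face; if
#'   `NULL`, taken from `source$intensity`.
#' @param config a [detector_config()].
#' @param duration acquisition real time in seconds (> 0).
#' @param attenuation_table attenuation table for absorption thinning;
#'   `NULL` disables thinning. Default: packaged LYSO table.
#' @param seed optional integer seed.
#' @return object of class `pulse_stream`: list with `timestamps` (s,
#'   ascending), `adc` (integer bins in `[0, n_bins)`), `true_keV` (ground
#'   truth energy of each accepted pulse), `dropped_count` (lost to
#'   deadtime), `subthreshold_count`, `absorbed_count`, `arrival_count`,
#'   `duration`, and the `config` used.
#' @examples
#' cfg <- detector_config(resolution_sigma = 0, threshold = 0)
#' s <- detect_and_digitize(source_monoenergetic(60), 1000, cfg, 0.5,
#'                          attenuation_table = NULL, seed = 1)
#' unique(s$adc)  # round(10 * 60 + 10)
#' @export
detect_and_digitize <- function(source, arrival_rate = NULL, config,
                                duration, attenuation_table,
                                seed = NULL) {
  stopifnot(inherits(config, "detector_config"))
  if (missing(attenuation_table)) {
    attenuation_table <- scintdose_tables()$attenuation
  }
  if (is.null(arrival_rate)) {
    if (!inherits(source, "source_model")) {
      stop("arrival_rate is required when source is a plain energy vector")
    }
    arrival_rate <- source$intensity
  }
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    stop("duration must be a positive scalar")
  }
  if (arrival_rate < 0) stop("arrival_rate must be non-negative")
  if (!is.null(seed)) set.seed(seed)

  n_arrivals <- rpois(1, arrival_rate * duration)
  empty <- function() {
    structure(list(timestamps = numeric(0), adc = integer(0),
                   true_keV = numeric(0), dropped_count = 0L,
                   subthreshold_count = 0L, absorbed_count = 0L,
                   arrival_count = n_arrivals, duration = duration,
                   config = config),
              class = "pulse_stream")
  }
  if (n_arrivals == 0) return(empty())

  t <- sort(runif(n_arrivals, 0, duration))
  e <- if (inherits(source, "source_model")) {
    sample_source(source, n_arrivals)
  } else {
    if (!is.numeric(source) || !length(source)) {
      stop("unknown source kind")
    }
    if (length(source) == 1L) rep(source, n_arrivals)
    else sample(source, n_arrivals, replace = TRUE)
  }

  # absorption thinning
  if (!is.null(attenuation_table)) {
    eta <- absorption_efficiency(e, config$geometry, attenuation_table)
    keep <- runif(n_arrivals) < eta
    t <- t[keep]; e <- e[keep]
  }
  n_absorbed <- length(e)
  if (!n_absorbed) return(empty())

  # analog amplitude with Gaussian resolution
  a0 <- config$gain_a * e + config$gain_b
  amp <- a0 + rnorm(n_absorbed, 0, amplitude_sigma(config, a0))

  # comparator: sub-threshold pulses do not trigger sampling
  trig <- amp > config$threshold
  n_sub <- sum(!trig)
  t <- t[trig]; e <- e[trig]; amp <- amp[trig]

  if (!length(t)) {
    out <- empty()
    out$subthreshold_count <- as.integer(n_sub)
    out$absorbed_count <- as.integer(n_absorbed)
    return(out)
  }

  proc <- process_pulse_train(t, amp, config$tau, config$pileup_enabled)
  adc <- as.integer(round(proc$amplitude))
  adc[adc < 0L] <- 0L
  adc[adc >= config$n_bins] <- config$n_bins - 1L

  structure(list(timestamps = proc$time, adc = adc,
                 true_keV = e[proc$index],
                 dropped_count = as.integer(proc$dropped),
                 subthreshold_count = as.integer(n_sub),
                 absorbed_count = as.integer(n_absorbed),
                 arrival_count = n_arrivals, duration = duration,
                 config = config),
            class = "pulse_stream")
}

#' @export
print.pulse_stream <- function(x, ...) {
  cat(sprintf(paste0("<pulse_stream: %d accepted / %d absorbed pulses in ",
                     "%.3g s (%d dropped, %d sub-threshold)>\n"),
              length(x$adc), x$absorbed_count, x$duration,
              x$dropped_count, x$subthreshold_count))
  invisible(x)
}

#' Read / write pulse streams as CSV
#'
#' Streams are exchanged as `t_s,adc,true_keV` CSV files (ground-truth energy
#' is `NA` for recorded, non-simulated streams).
#'
#' @param stream a `pulse_stream`.
#' @param path file path.
#' @param duration,config acquisition metadata to attach on read (the CSV
#'   stores the pulse list only).
#' @return `read_pulse_stream` returns a `pulse_stream`.
#' @export
write_pulse_stream <- function(stream, path) {
  stopifnot(inherits(stream, "pulse_stream"))
  df <- data.frame(t_s = stream$timestamps, adc = stream$adc,
                   true_keV = stream$true_keV)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pulse_stream
#' @export
read_pulse_stream <- function(path, duration = NULL,
                              config = detector_config()) {
  df <- read.csv(path)
  if (!all(c("t_s", "adc") %in% names(df))) {
    stop("pulse stream CSV needs columns t_s and adc")
  }
  if (is.null(duration)) {
    duration <- if (nrow(df)) max(df$t_s) else 0
  }
  structure(list(timestamps = df$t_s, adc = as.integer(df$adc),
                 true_keV = if ("true_keV" %in% names(df)) df$true_keV
                            else rep(NA_real_, nrow(df)),
                 dropped_count = NA_integer_,
                 subthreshold_count = NA_integer_,
                 absorbed_count = NA_integer_,
                 arrival_count = NA_integer_,
                 duration = duration, config = config),
            class = "pulse_stream")
}
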