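#' Am-241 auto-calibration
#'
#' The device is energy-calibrated from any Am-241 source (e.g. an ionization
#' smoke-detector capsule): the pulse-height histogram shows two major peaks,
#' the 59.5 keV gamma line and the envelope of the low-energy (10-23 keV)
#' emission lines, whose smeared maximum is taken to lie at 19 keV. A linear
#' ADC-to-energy relationship is assumed, so the two detected peak bins and
#' the two anchor energies determine the affine map `E = a * bin + b`
#' exactly. The procedure is: acquire until the maximum bin count reaches a
#' stop limit, moving-average smooth, locate the two most prominent peaks,
#' and solve the two-point line.
#'
#' @name calibration
NULL

#' Acquire a calibration histogram with a stop rule
#'
#' Simulates acquisition from a source, stopping the moment the maximum
#' single-bin count reaches `stop_count` (the returned histogram's maximum
#' equals `stop_count` exactly and its real time is the timestamp of the
#' pulse that reached it), or at `timeout_s` with a `timeout` attribute set.
#' On timeout with fewer than `min_counts` in the maximum bin the
#' acquisition is deemed unusable and an error of class
#' `scintdose_insufficient_statistics` is raised (the physical device
#' re-prompts the user); set `min_counts = 0` to always receive the
#' histogram.
#'
#' @param source a `source_model` (typically [source_am241()]).
#' @param config a [detector_config()].
#' @param stop_count stop when a bin reaches this count (default 50).
#' @param timeout_s acquisition time limit in seconds (default 60).
#' @param chunk_s simulation chunk length in seconds.
#' @param min_counts minimum usable maximum-bin count at timeout.
#' @param attenuation_table passed to [detect_and_digitize()].
#' @param seed optional integer seed.
#' @return a [pulse_histogram()] with attributes `timeout` (logical) and
#'   `stop_count`.
#' @export
acquire_calibration <- function(source, config = detector_config(),
                                stop_count = 50, timeout_s = 60,
                                chunk_s = 1, min_counts = 10,
                                attenuation_table, seed = NULL) {
  if (stop_count < 1) stop("stop_count must be >= 1")
  if (timeout_s <= 0) stop("timeout_s must be positive")
  if (missing(attenuation_table)) {
    attenuation_table <- scintdose_tables()$attenuation
  }
  if (!is.null(seed)) set.seed(seed)

  adc <- integer(0)
  times <- numeric(0)
  elapsed <- 0
  while (elapsed < timeout_s) {
    step <- min(chunk_s, timeout_s - elapsed)
    chunk <- detect_and_digitize(source, NULL, config, step,
                                 attenuation_table = attenuation_table)
    adc <- c(adc, chunk$adc)
    times <- c(times, elapsed + chunk$timestamps)
    elapsed <- elapsed + step
    if (length(adc)) {
      # occurrence index of each pulse within its own bin, in arrival order
      occ <- stats::ave(seq_along(adc), adc, FUN = seq_along)
      hit <- which(occ >= stop_count)
      if (length(hit)) {
        k <- hit[1]
        hist <- pulse_histogram(tabulate(adc[seq_len(k)] + 1L,
                                         nbins = config$n_bins),
                                real_time = times[k], tau = config$tau)
        attr(hist, "timeout") <- FALSE
        attr(hist, "stop_count") <- stop_count
        return(hist)
      }
    }
  }
  max_count <- if (length(adc)) max(tabulate(adc + 1L, config$n_bins)) else 0
  if (max_count < min_counts) {
    stop(structure(class = c("scintdose_insufficient_statistics",
                             "error", "condition"),
                   list(message = sprintf(
                     paste0("calibration acquisition timed out after %g s ",
                            "with maximum bin count %d < %d: insufficient ",
                            "statistics"), timeout_s, max_count, min_counts),
                     call = sys.call(-1))))
  }
  hist <- pulse_histogram(tabulate(adc + 1L, nbins = config$n_bins),
                          real_time = timeout_s, tau = config$tau)
  attr(hist, "timeout") <- TRUE
  attr(hist, "stop_count") <- stop_count
  hist
}

#' Moving-average smoothing of a histogram
#'
#' Centered moving average with an odd window; at the edges the window
#' shrinks symmetrically-as-possible (the average runs over the available
#' bins), so total mass is conserved up to edge effects within `window/2`
#' bins of either end.
#'
#' @param counts numeric vector of bin counts (or a [pulse_histogram()]).
#' @param window odd integer window width >= 1; must not exceed the
#'   histogram length.
#' @return real-valued smoothed counts, same length.
#' @examples
#' smooth_histogram(c(0, 0, 9, 0, 0), window = 3)
#' @export
smooth_histogram <- function(counts, window = 7) {
  if (inherits(counts, "pulse_histogram")) counts <- counts$counts
  n <- length(counts)
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  if (window > n) stop("window larger than histogram")
  if (window == 1) return(as.numeric(counts))
  half <- (window - 1L) / 2L
  cs <- cumsum(c(0, counts))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Local maxima of a numeric vector, plateau-aware. Returns 1-based indices
# (plateau center) of runs strictly greater than both neighboring runs;
# boundary runs qualify if greater than their single inner neighbor.
local_maxima <- function(x) {
  r <- rle(as.numeric(x))
  v <- r$values
  k <- length(v)
  if (k == 1) return(integer(0))
  left <- c(-Inf, v[-k])
  right <- c(v[-1], -Inf)
  is_max <- v > left & v > right
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  as.integer(floor((starts[is_max] + ends[is_max]) / 2))
}

# Topographic prominence of a peak at index i: height minus the higher of
# the two interval minima, where each interval extends to the nearest
# strictly higher point on that side (or the signal end). A boundary peak
# has no interval on its outer side; only the inner side constrains it.
peak_prominence <- function(x, i) {
  h <- x[i]
  n <- length(x)
  lmin <- if (i == 1L) -Inf else {
    lhigher <- which(x[seq_len(i - 1L)] > h)
    lstart <- if (length(lhigher)) max(lhigher) + 1L else 1L
    min(x[lstart:(i - 1L)])
  }
  rmin <- if (i == n) -Inf else {
    rel <- which(x[(i + 1L):n] > h)
    rend <- if (length(rel)) i + min(rel) - 1L else n
    min(x[(i + 1L):rend])
  }
  h - max(lmin, rmin)
}

# Sub-bin peak localization: value-weighted centroid of the contiguous bins
# around the mode that stay above half maximum without rising again (so the
# region never leaks into a neighboring peak). Returns a 0-based bin.
peak_centroid <- function(x, i) {
  h <- x[i]
  l <- i
  while (l > 1 && x[l - 1] >= h / 2 && x[l - 1] <= x[l]) l <- l - 1L
  r <- i
  n <- length(x)
  while (r < n && x[r + 1] >= h / 2 && x[r + 1] <= x[r]) r <- r + 1L
  w <- x[l:r]
  sum((l:r - 1) * w) / sum(w)
}

#' Locate the two calibration peaks
#'
#' Finds the two most prominent local maxima of a smoothed histogram,
#' subject to a minimum mutual separation and a prominence floor (a fraction
#' of the global maximum). Peak positions are reported either as the raw
#' mode (`"argmax"`) or as the value-weighted centroid of the bins within
#' the peak's half-maximum (`"centroid"`, default — reduces quantization
#' error).
#'
#' @param smoothed numeric vector of smoothed counts.
#' @param min_separation minimum distance between the two peaks, in bins.
#' @param min_prominence prominence floor as a fraction of the global
#'   maximum (default 0.10).
#' @param peak_mode `"centroid"` or `"argmax"`.
#' @return numeric vector `c(bin_low, bin_high)` of 0-based (possibly
#'   fractional) bins, `bin_low < bin_high`.
#' @export
find_calibration_peaks <- function(smoothed, min_separation = 10,
                                   min_prominence = 0.10,
                                   peak_mode = c("centroid", "argmax")) {
  peak_mode <- match.arg(peak_mode)
  x <- as.numeric(smoothed)
  cand <- local_maxima(x)
  cand <- cand[x[cand] > 0]
  if (length(cand) >= 2) {
    prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
    keep <- prom >= min_prominence * max(x)
    cand <- cand[keep]; prom <- prom[keep]
  }
  if (length(cand) < 2) {
    stop("calibration failure: fewer than 2 qualifying peaks; ",
         "re-acquire the calibration histogram")
  }
  ord <- order(prom, decreasing = TRUE)
  chosen <- integer(0)
  for (i in cand[ord]) {
    if (all(abs(i - chosen) >= min_separation)) chosen <- c(chosen, i)
    if (length(chosen) == 2) break
  }
  if (length(chosen) < 2) {
    stop("calibration failure: fewer than 2 qualifying peaks separated by ",
         min_separation, " bins; re-acquire the calibration histogram")
  }
  chosen <- sort(chosen)
  pos <- if (peak_mode == "argmax") as.numeric(chosen - 1L)
         else vapply(chosen, function(i) peak_centroid(x, i), numeric(1))
  sort(pos)
}

#' Two-point linear energy calibration
#'
#' Solves the affine ADC-to-energy map through the two anchor points:
#' `a = (E_high - E_low) / (bin_high - bin_low)`, `b = E_low - a * bin_low`.
#' The map reproduces both anchors exactly by construction. Its valid energy
#' range is the ADC range `[map(0), map(n_bins - 1)]` clipped to the physics
#' tables' coverage — outside it the device cannot reliably attribute photon
#' energies.
#'
#' @param bin_low,bin_high detected peak bins (0-based, `bin_low <
#'   bin_high`).
#' @param e_low,e_high anchor energies in keV (defaults 19 and 59.5, the
#'   Am-241 envelope mode and gamma line).
#' @param n_bins histogram length the calibration applies to.
#' @param coverage energy coverage `c(min, max)` in keV to clip the valid
#'   range to; default: the packaged tables' common coverage.
#' @return object of class `energy_calibration`: fields `a` (keV/bin), `b`
#'   (keV), `valid_range` (keV), `peak_bins`, `anchors_keV`, `n_bins`.
#' @examples
#' cal <- fit_energy_calibration(200, 800)
#' cal$a                     # 40.5 / 600
#' apply_calibration(800, cal)  # 59.5
#' @export
fit_energy_calibration <- function(bin_low, bin_high,
                                   e_low = 19, e_high = 59.5,
                                   n_bins = 1024, coverage = NULL) {
  if (bin_low >= bin_high) {
    stop("degenerate fit: bin_low must be strictly below bin_high")
  }
  if (e_low >= e_high) stop("e_low must be strictly below e_high")
  a <- (e_high - e_low) / (bin_high - bin_low)
  b <- e_low - a * bin_low
  if (is.null(coverage)) coverage <- table_coverage(scintdose_tables())
  valid <- c(max(b, coverage[1]), min(a * (n_bins - 1) + b, coverage[2]))
  structure(list(a = a, b = b, valid_range = valid,
                 peak_bins = c(low = bin_low, high = bin_high),
                 anchors_keV = c(low = e_low, high = e_high),
                 n_bins = as.integer(n_bins)),
            class = "energy_calibration")
}

#' Apply an energy calibration to ADC bins
#'
#' Affine map `E = a * bin + b`. Energies outside the calibration's valid
#' range are flagged (attribute `in_range`), never errors.
#'
#' @param bins numeric vector of ADC bins (0-based; fractional allowed).
#' @param calibration an `energy_calibration`.
#' @return energies in keV with logical attribute `in_range`.
#' @export
apply_calibration <- function(bins, calibration) {
  stopifnot(inherits(calibration, "energy_calibration"))
  e <- calibration$a * bins + calibration$b
  attr(e, "in_range") <- e >= calibration$valid_range[1] &
    e <= calibration$valid_range[2]
  e
}

#' Calibrate from an Am-241 histogram
#'
#' The full auto-calibration on an acquired histogram: moving-average
#' smoothing, two-peak detection, two-point linear fit.
#'
#' @param histogram a [pulse_histogram()] (a raw Am-241 acquisition).
#' @param window smoothing window (odd, default 7).
#' @inheritParams find_calibration_peaks
#' @inheritParams fit_energy_calibration
#' @return an `energy_calibration`.
#' @export
calibrate_histogram <- function(histogram, window = 7,
                                e_low = 19, e_high = 59.5,
                                min_separation = 10, min_prominence = 0.10,
                                peak_mode = c("centroid", "argmax"),
                                coverage = NULL) {
  stopifnot(inherits(histogram, "pulse_histogram"))
  sm <- smooth_histogram(histogram$counts, window)
  peaks <- find_calibration_peaks(sm, min_separation, min_prominence,
                                  match.arg(peak_mode))
  fit_energy_calibration(peaks[1], peaks[2], e_low, e_high,
                         n_bins = histogram$n_bins, coverage = coverage)
}

#' @export
print.energy_calibration <- function(x, ...) {
  cat(sprintf(paste0("<energy_calibration: E = %.5g * bin + %.5g keV, ",
                     "valid %.4g-%.4g keV, peaks (%.4g, %.4g)>\n"),
              x$a, x$b, x$valid_range[1], x$valid_range[2],
              x$peak_bins[1], x$peak_bins[2]))
  invisible(x)
}

#' Persist a calibration as JSON
#'
#' Software analog of storing the `[a, b]` parameters in device flash:
#' round-trips all fields losslessly.
#'
#' @param calibration an `energy_calibration`.
#' @param path JSON file path.
#' @return `load_calibration` returns an `energy_calibration`.
#' @export
save_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "energy_calibration"))
  payload <- list(a = calibration$a, b = calibration$b,
                  valid_range = calibration$valid_range,
                  peak_bins = as.numeric(calibration$peak_bins),
                  anchors_keV = as.numeric(calibration$anchors_keV),
                  n_bins = calibration$n_bins,
                  timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(a = p$a, b = p$b, valid_range = p$valid_range,
                 peak_bins = c(low = p$peak_bins[1], high = p$peak_bins[2]),
                 anchors_keV = c(low = p$anchors_keV[1],
                                 high = p$anchors_keV[2]),
                 n_bins = as.integer(p$n_bins)),
            class = "energy_calibration")
}
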