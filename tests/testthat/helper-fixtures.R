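# Shared fixtures: packaged tables, standard configs, and independent
# brute-force oracles used to cross-check the package's algorithms.

tabs <- load_tables()
geo_default <- detector_geometry()

# packaged table rows used for hand evaluations (transcribed from the CSVs,
# not read through the interpolator)
MU_LYSO_60 <- 1.725   # 1/mm at 60 keV
E_ICRP_60 <- 0.390    # pSv cm2 at 60 keV, AP

# write a small physics CSV and return its path
write_table_csv <- function(energies, values, header = "energy_keV,value") {
  path <- tempfile(fileext = ".csv")
  writeLines(c(header, paste(energies, values, sep = ",")), path)
  path
}

# Brute-force peak oracle: enumerate strict local maxima, compute
# topographic prominence by direct scanning, rank by prominence, and pick
# greedily under the separation rule. Written independently of the package
# implementation; assumes no plateaus (fixtures add jitter).
brute_force_peaks <- function(x, min_separation = 10, min_prominence = 0.10) {
  n <- length(x)
  maxima <- which(vapply(seq_len(n), function(i) {
    left <- if (i == 1) -Inf else x[i - 1]
    right <- if (i == n) -Inf else x[i + 1]
    x[i] > left && x[i] > right
  }, logical(1)))
  maxima <- maxima[x[maxima] > 0]
  prom <- vapply(maxima, function(i) {
    lmin <- if (i == 1) -Inf else {
      j <- i
      m <- x[j - 1]
      while (j > 1 && x[j - 1] <= x[i]) {
        j <- j - 1
        m <- min(m, x[j])
      }
      m
    }
    rmin <- if (i == n) -Inf else {
      j <- i
      m <- x[j + 1]
      while (j < n && x[j + 1] <= x[i]) {
        j <- j + 1
        m <- min(m, x[j])
      }
      m
    }
    x[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence * max(x)
  maxima <- maxima[keep]
  prom <- prom[keep]
  chosen <- integer(0)
  for (i in maxima[order(prom, decreasing = TRUE)]) {
    if (all(abs(i - chosen) >= min_separation)) chosen <- c(chosen, i)
    if (length(chosen) == 2) break
  }
  sort(chosen) - 1  # 0-based bins
}

# synthetic smoothed histogram: a mixture of Gaussian bumps plus jitter
# (jitter breaks plateaus so strict local-maximum definitions coincide)
random_bump_histogram <- function(n_bins = 64, n_bumps = 3) {
  x <- numeric(n_bins)
  centers <- sample(seq(5, n_bins - 5), n_bumps)
  for (c in centers) {
    amp <- runif(1, 20, 100)
    width <- runif(1, 1.5, 4)
    x <- x + amp * exp(-((seq_len(n_bins) - c)^2) / (2 * width^2))
  }
  x + runif(n_bins, 0, 1e-6)
}

# exact calibration for a known simulator gain: anchor bins evaluated from
# the true (noise-free) gain so the fitted map is the exact inverse
exact_calibration <- function(config, coverage = NULL) {
  fit_energy_calibration(config$gain_a * 19 + config$gain_b,
                         config$gain_a * 59.5 + config$gain_b,
                         n_bins = config$n_bins, coverage = coverage)
}
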