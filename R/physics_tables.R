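#' Energy-indexed physics tables
#'
#' The dose pipeline rests on two tabulated physics inputs: the linear
#' attenuation coefficient of the LYSO crystal, `mu(E)` (1/mm), from which the
#' absorption efficiency `eta(E) = 1 - exp(-mu(E) * t)` follows, and the
#' ICRP 116 anteroposterior effective-dose-per-fluence coefficients `e(E)`
#' (pSv cm^2). Both are packaged as plain CSV files with `#` provenance
#' headers and interpolated log-log between grid points, the standard choice
#' for photon cross sections, which are near power-law in energy. The grids
#' bracket the Lu K-edge (63.31 keV) with points immediately below and above
#' it so that interpolation never bridges the discontinuity.
#'
#' Energies outside a table's grid raise an error naming the grid bounds:
#' the calibration defines the spectral range over which the device can
#' attribute photon energies, and extrapolating beyond the tabulated range
#' would silently fabricate physics.
#'
#' @name physics_tables
NULL

#' Load an energy-indexed physics table from CSV
#'
#' Reads a two-column CSV (`energy_keV,<value>`, `#` comments allowed) and
#' validates it: strictly increasing energy grid, all values positive, no
#' duplicated energies. Malformed rows are reported with their row number.
#'
#' @param path path to the CSV file.
#' @param kind `"attenuation"` (values are mu in 1/mm) or `"dose"` (values are
#'   pSv cm^2); controls the class of the returned table.
#' @return an object of class `physics_table` (and `attenuation_table` or
#'   `dose_coefficient_table`): a list with `energies` (keV) and `values`.
#' @export
load_physics_table <- function(path, kind = c("attenuation", "dose")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("physics table not found: ", path)
  raw <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) != 2) stop("expected 2 columns in ", path, ", got ", ncol(raw))
  e <- suppressWarnings(as.numeric(raw[[1]]))
  v <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(!is.finite(e) | !is.finite(v))
  if (length(bad)) {
    stop("non-numeric entry in ", path, " at data row ", bad[1])
  }
  if (anyDuplicated(e)) {
    stop("duplicate energy in ", path, " at data row ",
         which(duplicated(e))[1])
  }
  if (is.unsorted(e, strictly = TRUE)) {
    stop("energy grid not strictly increasing in ", path, " at data row ",
         which(diff(e) <= 0)[1] + 1L)
  }
  neg <- which(v <= 0)
  if (length(neg)) {
    stop("non-positive value in ", path, " at data row ", neg[1])
  }
  structure(
    list(energies = e, values = v, source = path),
    class = c(if (kind == "attenuation") "attenuation_table"
              else "dose_coefficient_table",
              "physics_table"))
}

#' Load the attenuation and dose-coefficient tables
#'
#' Convenience loader for the pair of tables the dose engine needs. With no
#' arguments the CSVs packaged under `extdata` are used (LYSO attenuation and
#' ICRP 116 AP dose coefficients, both covering 10-200 keV).
#'
#' @param attenuation_path CSV with columns `energy_keV,mu_per_mm`.
#' @param coefficient_path CSV with columns `energy_keV,pSv_cm2`.
#' @return a list with elements `attenuation` and `dose`.
#' @examples
#' tabs <- load_tables()
#' range(tabs$attenuation$energies)
#' @export
load_tables <- function(attenuation_path = NULL, coefficient_path = NULL) {
  if (is.null(attenuation_path)) {
    attenuation_path <- system.file("extdata", "lyso_attenuation.csv",
                                    package = "scintdose", mustWork = TRUE)
  }
  if (is.null(coefficient_path)) {
    coefficient_path <- system.file("extdata", "icrp116_ap_dose.csv",
                                    package = "scintdose", mustWork = TRUE)
  }
  list(attenuation = load_physics_table(attenuation_path, "attenuation"),
       dose = load_physics_table(coefficient_path, "dose"))
}

# Memoized packaged tables; loading the CSVs once per session is enough.
scintdose_tables <- function() {
  if (is.null(.scintdose_env$tables)) {
    .scintdose_env$tables <- load_tables()
  }
  .scintdose_env$tables
}

# Log-log piecewise-linear interpolation on a physics table. Hard error
# outside the grid. Exact at grid nodes. Because the K-edge is bracketed by
# two grid points, each interpolation segment lies entirely on one side of
# the edge.
interp_table <- function(table, energy) {
  stopifnot(inherits(table, "physics_table"))
  if (!length(energy)) return(numeric(0))
  if (any(!is.finite(energy)) || any(energy <= 0)) {
    stop("energies must be positive and finite")
  }
  lo <- table$energies[1]
  hi <- table$energies[length(table$energies)]
  out <- which(energy < lo | energy > hi)
  if (length(out)) {
    stop(sprintf(
      "energy %.4g keV outside table grid [%.4g, %.4g] keV",
      energy[out[1]], lo, hi))
  }
  exp(approx(log(table$energies), log(table$values), log(energy),
             ties = "ordered")$y)
}

#' Table energy coverage
#'
#' Energy interval (keV) over which all supplied tables are defined; dose
#' conversion is restricted to this range.
#'
#' @param ... one or more `physics_table` objects, or lists of them.
#' @return numeric length-2 vector `c(min, max)` in keV.
#' @export
table_coverage <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && !inherits(tabs[[1]], "physics_table")) {
    tabs <- tabs[[1]]
  }
  lo <- max(vapply(tabs, function(t) t$energies[1], numeric(1)))
  hi <- min(vapply(tabs, function(t) t$energies[length(t$energies)],
                   numeric(1)))
  c(lo, hi)
}

#' Detector crystal geometry
#'
#' @param area_mm2 face area of the crystal in mm^2 (default 25, a 5 x 5 mm
#'   crystal).
#' @param thickness_mm crystal thickness in mm (default 1).
#' @return object of class `detector_geometry`.
#' @export
detector_geometry <- function(area_mm2 = 25, thickness_mm = 1) {
  if (!is.numeric(area_mm2) || length(area_mm2) != 1 || area_mm2 <= 0) {
    stop("area_mm2 must be a positive scalar")
  }
  if (!is.numeric(thickness_mm) || length(thickness_mm) != 1 ||
      thickness_mm < 0) {
    stop("thickness_mm must be a non-negative scalar")
  }
  structure(list(area_mm2 = area_mm2, thickness_mm = thickness_mm),
            class = "detector_geometry")
}

#' Photon absorption efficiency of the crystal
#'
#' Probability that a photon of the given energy interacts in a slab crystal
#' of the given thickness: `eta(E) = 1 - exp(-mu(E) * t)`, with `mu`
#' interpolated log-log on the attenuation grid. Vectorized over `energy`.
#'
#' @param energy photon energy (keV), within the table grid.
#' @param geometry a [detector_geometry()].
#' @param table an `attenuation_table`; default: packaged LYSO table.
#' @return efficiency in `(0, 1]` (0 exactly when `thickness_mm = 0`).
#' @examples
#' absorption_efficiency(60, detector_geometry())
#' @export
absorption_efficiency <- function(energy, geometry = detector_geometry(),
                                  table = scintdose_tables()$attenuation) {
  stopifnot(inherits(geometry, "detector_geometry"))
  mu <- interp_table(table, energy)
  1 - exp(-mu * geometry$thickness_mm)
}

#' Effective dose per photon incident on the detector face
#'
#' `e(E) / A`: the ICRP 116 AP fluence-to-effective-dose coefficient at the
#' given energy divided by the crystal face area in cm^2. A photon incident
#' on the face represents a fluence of `1/A` per cm^2, so halving the area
#' doubles the dose attributed per photon.
#'
#' @param energy photon energy (keV), within the table grid.
#' @param geometry a [detector_geometry()]; `area_mm2` is converted to cm^2.
#' @param table a `dose_coefficient_table`; default: packaged ICRP 116 AP
#'   table.
#' @return dose per incident photon in pSv, vectorized over `energy`.
#' @examples
#' per_photon_dose(60, detector_geometry())  # 0.39 pSv cm2 / 0.25 cm2
#' @export
per_photon_dose <- function(energy, geometry = detector_geometry(),
                            table = scintdose_tables()$dose) {
  stopifnot(inherits(geometry, "detector_geometry"))
  e <- interp_table(table, energy)
  area_cm2 <- geometry$area_mm2 / 100
  e / area_cm2
}
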