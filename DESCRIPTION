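Package: scintdose
Title: Scintillator Pulse-Height Dosimetry with Am-241 Energy Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline of a scintillator-based (LYSO + SiPM)
    personal X-ray dosimeter: energy-indexed physics tables (LYSO photon
    absorption efficiency, ICRP 116 anteroposterior fluence-to-effective-dose
    coefficients) with log-log interpolation, a Monte-Carlo pulse-train
    simulator (Am-241 and filtered X-ray tube sources, Poisson arrivals,
    Gaussian pulse-height resolution, trigger threshold, non-paralyzable
    deadtime, optional amplitude pile-up), pulse-height histogram acquisition
    with deadtime-fraction estimation and count correction, automatic two-peak
    Am-241 energy calibration (moving-average smoothing, prominence-based peak
    detection, two-point linear ADC-to-energy fit anchored at 19 and 59.5 keV),
    spectrum-to-effective-dose conversion with dose-rate and accumulated-dose
    tracking, and a software emulation of the device runtime (single-button
    state machine, 1 Hz sampling, 10-hour ring-buffer log).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
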