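# scintdose

Computational pipeline of a scintillator-based personal X-ray dosimeter,
implemented as a tested R package with a Monte-Carlo pulse-train simulator
standing in for the physical detector. It is aimed at health-physics and
instrumentation work: prototyping and validating the algorithms a low-cost
LYSO + SiPM dosimeter runs on-device — Am-241 spectral auto-calibration,
pulse-height-spectrum-to-effective-dose conversion, and non-paralyzable
deadtime handling — without needing hardware.

## The model

A photon of energy *E* (keV) incident on a slab crystal of thickness *t*
interacts with probability

> η(E) = 1 − exp(−μ(E)·t),

where μ(E) is the LYSO linear attenuation coefficient (packaged table,
log-log interpolated; the Lu K-edge at 63.31 keV is bracketed by grid points
so interpolation never bridges it). Detected pulses are digitized through an
affine gain `adc = a′·E + b′` with Gaussian resolution and a trigger
threshold; each accepted pulse blocks the processor for τ seconds
(non-paralyzable), so the observed count rate follows

> n_out = n_in / (1 + n_in·τ),  saturating at 1/τ (≈ 77 kcps at τ = 13 μs),

with deadtime fraction `f = n_out·τ` used as the count correction
`1/(1 − f)`.

Energy calibration uses any Am-241 source: the pulse-height histogram is
acquired until the maximum bin reaches a stop count, moving-average
smoothed, and its two most prominent peaks are anchored to 19 keV (the
low-energy emission envelope) and 59.5 keV (the gamma line), giving the
linear map `E = a·bin + b` exactly through both anchors.

The effective-dose increment of a calibrated window is

> ΔD = Σ_bins  counts(bin)/(1 − f) · 1/η(E(bin)) · e(E(bin))/A,

where e(E) is the ICRP 116 anteroposterior effective-dose-per-fluence
coefficient (pSv·cm², packaged table) and A the crystal face area in cm².
Dose rate is ΔD/Δt scaled to Sv/h; accumulated dose is the running sum. A
software device runtime adds the single-button state machine, 1 Hz
sampling, and a 10-hour ring-buffer dose log.

## Worked example

```r
library(scintdose)
set.seed(7)

cfg  <- detector_config()                  # 25 mm2 x 1 mm LYSO, tau = 13 us
hist <- acquire_calibration(source_am241(2e4), cfg)
hist
#> <pulse_histogram: 1024 bins, 7961 counts, 0.53 s, 1.502e+04 cps, deadtime 19.53%>
cal <- calibrate_histogram(hist)
cal
#> <energy_calibration: E = 0.093173 * bin + 1.1066 keV, valid 10-96.42 keV, peaks (192, 626.7)>

src       <- source_tube(120, 2)           # 120 kV tube, 2 mm Pb filtration
intensity <- intensity_for_dose_rate(src, 10)   # photons/s giving 10 uSv/h
stream    <- detect_and_digitize(src, intensity, cfg, 60)
d         <- spectrum_dose(build_histogram(stream, cfg), cal)
dose_rate(as.numeric(d), 60) * 1e6
#> [1] 9.676
```

The acquisition stopped at a maximum bin count of 50 after 0.53 s; the
fitted calibration maps its detected peak bins (192, 626.7) to the 19 and
59.5 keV anchors, approximating the inverse of the simulator's true gain
(10 bins/keV, offset 10). The 60 s exposure whose analytic ground-truth
dose rate is 10 μSv/h is estimated at 9.68 μSv/h after deadtime and
efficiency correction — a −3% error, dominated by calibration quantization
and counting statistics.

A thin command-line entry point wraps the same functions:

```sh
exec/scintdose simulate   --config run.yaml --duration 10 --out stream.csv
exec/scintdose calibrate  --config run.yaml --out calibration.json
exec/scintdose run        --config run.yaml --duration 60 --out dose_log.csv
exec/scintdose characterize count-rate --rates 1e4,1e5,1e6 --out rates.csv
```

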