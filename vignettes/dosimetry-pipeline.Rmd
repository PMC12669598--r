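---
title: "Methods: scintillator pulse-height dosimetry in scintdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scintillator pulse-height dosimetry in scintdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scintdose)
```

## The measurement model

scintdose models a wearable photon-counting dosimeter built from a small
LYSO scintillator crystal read out by a silicon photomultiplier. The chain
from photon to dose estimate is:

1. **Absorption.** A photon of energy $E$ interacts in the 1 mm slab with
   probability $\eta(E) = 1 - e^{-\mu(E)t}$. $\mu(E)$ comes from a packaged
   CSV table (provenance in its header comments) interpolated log-log.
2. **Digitization.** The scintillation pulse amplitude is affine in
   deposited energy, $\mathrm{adc} = a'E + b'$, smeared by Gaussian noise
   and accepted only above a comparator threshold. Amplitudes beyond the
   last histogram bin clamp there (pulse-height saturation).
3. **Deadtime.** Each accepted pulse occupies the processor for
   $\tau$ seconds (non-paralyzable): the observed rate is
   $n_\mathrm{out} = n_\mathrm{in}/(1 + n_\mathrm{in}\tau)$, saturating at
   $1/\tau$. The firmware-style deadtime estimate is
   $f = n_\mathrm{out}\tau$ and the count correction is $1/(1-f)$.
4. **Calibration.** Two detected Am-241 peaks are anchored at 19 and
   59.5 keV; the affine energy map follows exactly from the two points.
5. **Dose.** For each window, corrected counts are divided by $\eta(E)$
   (recovering incident photons) and weighted by the per-photon dose
   $e(E)/A$, where $e(E)$ is the ICRP 116 anteroposterior
   dose-per-fluence coefficient and $A$ the crystal face area. Summing
   bins gives the window's effective-dose increment; dividing by the
   window and scaling to hours gives the dose rate.

The package treats the AP effective dose as *the* dose quantity; other
geometries (PA/LAT/ISO) and operational quantities such as Hp(10) are out
of scope, as is oblique-incidence (angular) response.

## Units

keV for energy, mm for crystal dimensions, cm² for areas in dose algebra
(converted internally from mm²), pSv for per-photon dose, Sv for reported
doses and increments, seconds for time, Sv/h for rates (µSv/h in logs and
characterization tables).

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| crystal area | 25 | mm² | 5 × 5 mm crystal face |
| crystal thickness | 1 | mm | sufficient absorption below ~140 keV |
| `tau` | 13e-6 | s | average per-pulse sampling time; sets the ~77 kcps ceiling |
| `gain_a`, `gain_b` | 10, 10 | bins/keV, bins | place 59.5 keV near bin 605 of 1024, i.e. a ~100 keV dynamic range |
| `resolution_sigma` | 60 | bins at the 59.5 keV amplitude | ≈23% FWHM at 59.5 keV, typical of a small LYSO + SiPM channel; scales as $\sqrt{\mathrm{amplitude}}$ per counting statistics |
| `threshold` | 50 | bins | ~4–5 keV noise floor |
| `n_bins` | 1024 | — | ADC depth; configurable |
| smoothing window | 7 | bins | wide enough to suppress bin noise, far narrower than either calibration peak |
| peak separation / prominence | 10 bins / 10% of max | — | the two Am-241 peaks are hundreds of bins apart and comparable in height; these floors only reject noise ripples |
| stop count / timeout | 50 / 60 | counts / s | acquisition halts at a usable peak height within a reasonable time |
| efficiency floor | 0.01 | — | bins with $\eta < 1\%$ are excluded rather than divided, avoiding 100× amplification of stray counts |
| deadtime cap | 0.9 | — | beyond 90% deadtime the correction factor exceeds 10× and the output is declared unreliable |
| log retention / rate | 10 h / 1 Hz | — | 36,000-entry ring buffer |

## What the simulator emulates — and what it does not

The pulse simulator generates Poisson arrivals, samples energies from a
source model, thins by $\eta(E)$, applies the affine gain with
$\sqrt{A}$-scaled Gaussian resolution, drops sub-threshold pulses (which do
not open a dead window, since the comparator never fires), applies the
non-paralyzable deadtime, and optionally amplitude-sums coincident pulses
(pile-up, off by default). Three sources are provided:

* **monoenergetic** — oracles and unit tests;
* **Am-241** — the 59.54 keV gamma line plus a low-energy envelope of Np L
  X-ray lines. The physics here is partly empirical: the envelope's
  composition depends on source packaging and reflector choices, so the
  line weights are a documented default chosen to make the smeared
  envelope peak near 19 keV, matching the calibration anchor convention.
  They are a modeling convention, not decay data.
* **X-ray tube** — a Kramers continuum $(\mathrm{kVp}-E)/E$ attenuated by a
  lead slab (packaged Pb attenuation table), discretized at 0.25 keV.
  A physical caveat the tests make explicit: at 90–120 kV, millimetre-scale
  Pb filtration transmits only a narrow window just below the Pb K-edge
  (88 keV), so the model's spectrum-weighted mean energies sit in the
  high 70s to mid 80s of keV regardless of tube setting. Survey-meter
  "average energy" readouts of real beams are a different estimator and
  can report lower values; the package's ground truth is always computed
  from its own spectral model, never from instrument readings.

Not modeled: optical photon transport, SiPM microcell saturation and
temperature drift, analog shaping, the Lu-176 intrinsic background
(88/202/307 keV), and angular response. Consequently, passing tests
demonstrate the correctness of the *algorithms* under the stated
statistical model — they do not certify accuracy on a physical device,
where these effects add systematic terms.

## Numerical choices

* **Interpolation** is piecewise-linear in log-log for both physics
  tables: photon cross sections and dose coefficients are near power-law
  in energy, and this is the standard choice. Interpolation is exact at
  grid nodes. The Lu K-edge (63.31 keV) and Pb K-edge (88.00 keV) are
  bracketed by grid points 0.02 and 0.01 keV apart, so no interpolation
  segment bridges a discontinuity. The weak Y K-edge (17.04 keV, 4% of
  LYSO's mass) is deliberately smoothed over.
* **Out-of-range energies are hard errors**, not extrapolations: the
  calibration defines the range over which energies can be attributed,
  and dose conversion silently extrapolated beyond the tables would be
  fabricated physics. Within the dose sum, out-of-range bins are excluded
  and tallied in a discard counter instead (flag, not failure).
* **Peak localization** defaults to the value-weighted centroid of the
  bins within the peak's half-maximum (bounded so the region never climbs
  into a neighboring peak); the raw argmax is available via
  `peak_mode = "argmax"`. The centroid reduces quantization error for the
  broad, smooth calibration peaks; for a symmetric peak the two coincide.
* **Peak selection** takes the two most prominent strict local maxima
  (topographic prominence, plateau-aware; a boundary peak is constrained
  only by its inner side) subject to the separation and prominence
  floors; ties in a greedy prominence ordering resolve toward the earlier
  candidate, which is immaterial for the well-separated Am-241 peaks.
* **Bin energies are evaluated at bin centers** through the calibration
  map; whether firmware uses centers or edges is unspecified, and at
  1024 bins the half-bin difference is far below resolution smearing.
* **Deadtime correction is per-bin and uniform** (single-τ model, energy
  independent), applied before the efficiency correction; the two are
  multiplicative so the order is fixed only for reproducibility.
  Corrected counts stay real-valued — re-rounding would bias dose sums.
* **Degenerate inputs**: empty streams yield valid all-zero histograms;
  an all-zero histogram doses to exactly 0 Sv; coincident calibration
  peaks are a degenerate-fit error; acquisition timeout with a maximum
  bin below `min_counts` (default 10) raises an insufficient-statistics
  error, and `min_counts = 0` returns the histogram with a timeout flag
  instead.
* **Reset semantics**: the options-menu reset clears dose values and rate
  history but never the stored calibration, which persists (as JSON)
  across sessions the way device flash survives power cycling.

## Problem sizes in tests and the acceptance script

The suite exercises the saturation region with ~10⁷-pulse simulations
(10 s at 10⁶ photons/s), calibrations from ~7,000-count Am-241 histograms
(default stop rule), and dose-accuracy runs of 60 s per level over
0.1–1000 µSv/h — the largest level simulating roughly 9 × 10⁶ arrivals.
The monoenergetic dose oracle uses ~2,000–3,000 counts per energy at
20–120 keV, with a 3σ Poisson tolerance on the recovered dose rate, under
a configuration with 8 bins/keV gain (so 120 keV stays inside 1024 bins)
and moderate resolution (σ = 20 bins at the reference amplitude). These
sizes were chosen so statistical tolerances are meaningful while a full
run stays fast on a single CPU.

## Known limitations

* **Efficiency inversion under finite resolution is slightly biased near
  edges.** Counts are divided by $\eta$ at their *recorded* energy; with
  broad resolution, photons recorded across the Lu K-edge are divided by
  the wrong-side efficiency, biasing monoenergetic doses near 63 keV low
  by a percent-scale amount that grows with resolution width. Broad
  spectra average this out. The oracle tests therefore use a moderate
  resolution; the effect is inherent to the on-device algorithm, not an
  implementation artifact.
* **The 19 keV anchor is empirical.** The low-energy envelope's true mode
  depends on source packaging; an anchor error propagates into the energy
  scale and hence the dose. The package applies the convention as given
  and surfaces the uncertainty here rather than compensating for it.
* **High-rate operation relies on the single-τ non-paralyzable model.**
  Pile-up (amplitude summation) is available in the simulator but no
  pile-up *correction* is attempted; levels beyond the 90% deadtime cap
  are flagged unreliable rather than corrected.
* **Transcribed physics tables.** The packaged LYSO attenuation values
  are assembled from elemental data by the mixture rule with stated
  approximations (header comments); they are accurate to roughly the
  10% level at the low-energy end. Both truth and estimate in the
  self-consistency checks share these tables, so algorithmic conclusions
  are unaffected, but absolute device accuracy would warrant a
  metrology-grade table.
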