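---
title: "Methods and design choices in pamscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in pamscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamscape)
```

`pamscape` implements the computational chain of a long-term passive
acoustic monitoring (PAM) programme for cetaceans: calibration and effort
accounting, soundscape metrics, a simple event detector, sonar-equation
detection ranges by Monte Carlo, solar-referenced occurrence analysis, and
environmental compositing with nonparametric site comparisons. This
vignette records the models, the conventions and the genuinely open design
choices, and what the synthetic-data validation does and does not
demonstrate about real recordings.

## Calibration and effort accounting

Raw ADC counts are scaled to micropascals through a flat calibration chain:
counts → volts via the full-scale voltage and bit depth, volts → µPa via
`10^((S + G)/20)` with hydrophone sensitivity `S` (dB re 1 V/µPa) and analog
gain `G` (dB). A per-frequency response correction hook exists but ships as
the identity: field calibrations of autonomous recorders are commonly
reduced to a flat mean sensitivity, and nothing downstream assumes
otherwise. The inverse transform recovers counts to within one quantization
step, which the tests assert. When the true full-scale voltage is unknown,
`adc_fullscale_voltage` defaults to 1.0 V and is documented as a
placeholder — absolute levels are then offset but every relative quantity
(band elevations, SNRs, diel contrasts) is unaffected.

Deployment duration is plain date subtraction (`end − start`, exclusive).
Provider-quoted duration tables sometimes disagree with that arithmetic by
a few days (gaps, partial days, inclusive counting); `deployment_record()`
therefore stores a quoted `duration_printed` separately, and
`day_equivalents()` — duration × recorded fraction of the duty cycle —
prefers the quoted value so that inventories reproduce provider figures.
Rounding is to the nearest whole day, half away from zero: the only
convention consistent with quoted day-equivalents in the motivating
inventories (165.6 → 166, 163.35 → 163).

## Soundscape metrics

The working unit is the 1-minute averaged one-sided power spectral density:
1-s segments, Hamming window, 0.5-s hop, periodograms normalised by
`fs · Σw²` so that integrated PSD equals time-domain variance (Parseval;
tested at 5% on generated noise). Every segment whose *start* lies inside
the frame is counted, the final half-covered segment zero-padded, giving
120 averages per full frame. A strict full-window scheme would give 119;
the 120 convention was adopted deliberately and the trailing padded segment
biases the frame by under 0.02 dB. Short trailing frames at file edges are
computed from the segments available and carry a reduced `n_averages`.

Conventions: PSD in dB re 1 µPa²/Hz, SPL in dB re 1 µPa; band integration
is lower-inclusive, upper-exclusive on bin centers, so adjacent bands add
exactly in linear power; long-term spectral averages (LTSA) average frames
in the *linear* domain (a dB average would underweight loud frames and is
bounded-above by the linear mean). The Hamming window is used for all PSD
work for internal consistency with spectrogram practice in this field.

Band elevation — how far a decaband SPL series rises above its quiet
baseline — uses the 10th percentile of the series as baseline. That is
robust to a minority of loud frames but becomes biased when more than ~90%
of frames contain calls; the simulated seasons keep the occupied fraction
well below that.

Mooring/flow-noise contamination is flagged by a deliberately simple
screen: a frame is flagged when its band SPL (default 10–200 Hz) exceeds
the deployment median by a threshold. On symmetric noise a zero threshold
flags about half the frames, which the tests use as a sanity property.

## The band-energy detector

The operational detectors used by monitoring programmes are proprietary and
species-specific; `band_energy_detect()` is a documented, minimal stand-in
sufficient to close the simulate → detect loop: band-pass filter
(4th-order Butterworth), 1-s frames, in-band SPL against a running-median
background (60 frames), trigger at a fixed SNR threshold, adjacent triggers
merged at the peak frame. A running median tolerates sparse calls but is
defeated when calls saturate the window — a real limitation shared by
energy detectors, and the reason the end-to-end pipeline spaces injected
calls at a duty of 1/4. Precision/recall use greedy earliest-first
one-to-one matching within a tolerance (default one frame). Recall is
non-increasing in the threshold and injected calls 6 dB above threshold are
found in ≥95% of seeded trials; both are tested.

## Detection ranges by Monte Carlo

The passive sonar equation gives the received level `RL = SL − PL`; a call
is detectable when `RL ≥ NL + DT` (equality detects). `DT` defaults to
0 dB — the signal-processing threshold of a good automated detector, not an
animal's hearing threshold. The detection range for one draw is the largest
grid range at which the inequality holds; keeping the *outermost* grid
point preserves detectable shadow-zone rebounds under non-monotone
propagation loss, and is checked against an exhaustive scan.

The Monte Carlo engine propagates three sources of variability. Each
iteration samples one noise-level minute, `n_sl` Normal source levels and
`n_depth` depths from a discrete calling-depth distribution (defaults
10 000 iterations × 100 × 100). Detection is evaluated over the full
SL × depth cross within an iteration and probabilities are pooled over all
draws; the percentile range `R_P` is the largest grid range whose pooled
detection probability is at least `P`. Under this convention lower
probability levels give larger ranges (`R_0.1 ≥ R_0.5 ≥ R_0.9`), matching
the field practice of mapping the 10th-percentile (most permissive) range.
Pooling over draws was a genuine choice — per-iteration percentiles of a
draws distribution are an equally defensible reading — and is stated here
because results differ slightly between the two when noise is multimodal.

The draw order within an iteration (noise minute, then source levels, then
depths) is part of the function's contract: a brute-force triple loop that
replays the same RNG stream reproduces the probability curve to machine
precision, which is the engine's strongest test. Coupled-seed monotonicity
(ranges non-increasing in NL and DT, non-decreasing in SL) and exact
closed-form collapse in degenerate configurations (sd 0, point depth,
constant NL, spherical spreading → `r = 10^((SL−NL)/20)`) complete the
suite.

Propagation loss is a pluggable contract. The shipped geometric model is
`N log10(r) + α(f)·r/1000` with `N = 20` (spherical), `N = 10`
(cylindrical) or spherical-to-cylindrical beyond a transition range, and
Thorp volume absorption `α(f)`; absorption can be disabled for pure
spreading laws. Full parabolic-equation or ray-trace modelling is out of
scope, but `load_pl_grid()` ingests externally modelled loss tables
(radial, frequency, depth, range) and interpolates bilinearly in depth and
range, nearest in frequency, erroring outside the grid domain rather than
extrapolating. PL is evaluated at the band's geometric-center frequency; a
representative frequency must be chosen for band-level work, and the
geometric center is the standard choice for logarithmic spectra. The range
grid defaults to 10-m steps to 100 km. Exact ties across bands in
`rmax_over_bands()` report the lower-frequency band.

## Solar geometry and occurrence

Sunrise and sunset come from the NOAA solar-calculator algorithm (Julian
century, equation of time, solar declination, hour angle at zenith
90.833°, i.e. refraction plus solar semidiameter) evaluated in UTC, with
the ephemeris re-evaluated at the event estimate for three iterations;
agreement with an independently coded single-shot transcription of the
spreadsheet formulas is within 2 minutes, and equinox daylight at the
equator is 12 h plus the expected ~7 refraction minutes. Polar day and
night are flagged explicitly. All timestamps in the package are UTC — a
deliberate choice, since duty cycles and satellite composites are defined
in UTC and a local-time convention would shift diel labels by the
longitude-dependent offset; the light/dark classification is unaffected
because it derives from the solar events themselves.

Hour bins are labeled light when the hour *midpoint* lies in
`[sunrise, sunset)`; boundary hours are otherwise undefined and the
midpoint rule is the least biased single-label convention. Presence is
binary per hour and class, and every cell carries the recording-effort
fraction implied by the duty cycle, so all rates downstream are
effort-normalized (a raw option is a one-liner on the grid).

The diel contrast is an inference this package adds: monitoring studies
typically show diel panels without a named test. Night and day
effort-normalized presence rates are compared with a permutation test that
shuffles light/dark labels *within each day*, preserving the daily presence
pattern and seasonal trends; the two-sided p-value uses the add-one
correction. On 60-day null fixtures the test holds its 5% size within 2
percentage points over 200 seeds, and on fixtures with a night multiplier
of 3 it rejects in over 80% of seeds — both run as acceptance checks.

## Environmental compositing and site statistics

The composite calendar is the satellite ocean-color convention: 8-day
periods starting January 1 and restarting each January 1 (last period 5–6
days), so acoustic and environmental series share dates exactly.
Call-hour proportions per composite are presence-hours over effort-hours;
zero-effort composites are missing, not zero, and partially covered edge
windows are flagged. Gridded fields are attached to a mooring by an
unweighted mean over a 20 × 20 km box (plate-carrée distances; adequate at
this scale), and missing chl-a — common in winter at high latitude — is
median-imputed per site with flags, never touching observed values.

`kruskal_wallis()` wraps the base tie-corrected rank test; Dunn's post-hoc
pairwise Z uses the standard tie-corrected variance
`N(N+1)/12 − ΣT/(12(N−1))` and is implemented in the package (no installed
package provides it), verified against brute-force rank arithmetic and
antisymmetry. The multiplicity adjustment defaults to Holm — uniformly more
powerful than Bonferroni with the same family-wise guarantee, and the
natural default when the original analysis does not state its adjustment.
The quasi-binomial GAMM that such studies fit on the composite table is
deliberately out of scope: penalized-spline fitting is off-the-shelf
statistics, so `build_model_table()` exports the model-ready long table
plus descriptive Spearman correlations instead.

## The synthetic generators

The generators exist so every operation can be tested against known ground
truth; their defaults describe a plausible northeast-Pacific monitoring
scenario and are fixed rather than tunable per test.

* `sim_ambient()` filters white Gaussian noise through an FIR (designed
  with `signal::fir2`, 256–4096 taps by sample rate) whose magnitude
  follows the target PSD curve, with extra band-passed noise in
  contamination windows sized to raise the band by the stated dB. The
  Parseval identity is its oracle.
* Call templates are signal-processing stand-ins, not acoustic replicas:
  linear sweeps with a Hann² envelope (fin-like 20-Hz pulses), harmonic
  stacks whose weighted third harmonic can dominate (blue-whale-B-like
  tonals near 38–55 Hz), and exponentially damped sinusoids (clicks).
  `inject_calls()` scales each template so its in-band level exceeds the
  measured background by the requested SNR, and returns a truth log.
* `sim_occupancy()` draws an inhomogeneous Poisson event stream: a flat
  hourly rate inside day-of-year windows (wrapping the year end), times a
  night multiplier during dark hours as classified by the solar module.
* `sim_env()` produces 8-day SST sinusoids with Gaussian noise (default
  amplitude 4 °C, phase day 227 — a mid-August maximum) and chl-a as a
  baseline with Gaussian spring/fall bloom bumps, with winter values
  dropped at random to mimic low-sun-angle satellite gaps.

Every generator is a pure function of its spec and seed.

What passing these tests shows: the arithmetic, conventions and inference
machinery are correct on data whose generating process is known. What it
does not show: robustness to real-ocean features the generators omit —
non-Gaussian transient noise (ships, ice, rain), overlapping species,
detector confusion between call types, propagation ducts, and clock drift.
Conclusions about real recordings still require detector validation against
manual review.

## Problem sizes and numerics

The test and acceptance runs use deliberately scaled problem sizes chosen
to exercise every code path: 60-s to 30-min audio at 256–512 Hz for
spectral checks, 100-iteration Monte Carlo runs for brute-force equality
(the engine's vectorized path handles the full 10 000 × 100 × 100 default
in seconds), 60-day occurrence fixtures for diel calibration, and an
~8-week simulated season (one minute per hour, 256 Hz) for the end-to-end
pipeline. Numerical guards: PSD levels floor at the smallest double before
the dB transform; probability curves are exact weighted empirical
survivals (no smoothing); permutation p-values use the add-one correction;
`findInterval` does all threshold searches, so results are
reproducible and independent of floating-point comparison order.

## Known limitations

Flat hydrophone response only; no decidecade (third-octave) standard
banding; geometric propagation ignores bathymetry, sound-speed structure
and azimuth unless an external loss grid is supplied; the detector is not a
species classifier; the diel test assumes exchangeability of hour labels
within a day under the null; and the box average ignores map projection
distortion beyond the cosine correction, which is negligible at 20-km
scale but not at basin scale.
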