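---
title: "Methods: gas-exchange-driven cerebrovascular reactivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gas-exchange-driven cerebrovascular reactivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvreact)
```

# The measurement model

A breath-hold challenge alternates ~30-s voluntary apneas with 60–90 s
of free breathing over about ten minutes. Gas analyzers sampling at the
nostril report PO₂ and PCO₂ continuously; each respiratory cycle traces
a trapezoid between the inspired level (near ambient, read at end
inspiration) and the end-tidal plateau (read at end expiration). The
within-breath swings ΔPO₂ = inspired − expired PO₂ and ΔPCO₂ =
expired − inspired PCO₂ quantify the per-breath gas exchange, and their
ratio, the breath-by-breath O₂–CO₂ exchange ratio

$$\mathrm{bER} = \frac{\Delta P_{O_2}}{\Delta P_{CO_2}},$$

is the package's central regressor. The ratio form cancels
ventilatory-volume fluctuations common to both swings, which is why it
outperforms either swing alone — and why it is robust to the
whole-channel analyzer drift that contaminates end-tidal levels.

Processing follows the chain: technical-delay correction →
marker detection → per-breath metrics → interpolation across holds →
coupling with hemodynamics (correlation, wavelet coherence) → voxelwise
CVR mapping.

## Marker detection and its assumptions

End expiration is the local maximum of PCO₂ terminating the expiratory
plateau; end inspiration is the preceding local minimum. Detection runs
on the PCO₂ channel only (its plateaus are sharper) and PO₂ is read at
the PCO₂-derived timestamps, so both channels share one time base and
within-breath marker mismatch cannot occur. Peaks must exceed a
prominence of 25% of the trace's interquartile range and be separated by
at least 1.5 s; both are configurable, and both assume the trace is
dominated by breathing rather than noise (sample noise above roughly
2 mmHg at 50 Hz will defeat them).

Apneas are found as near-flat runs of the heavily smoothed trace slope
(|slope| < 0.3 mmHg/s for ≥ 10 s, sub-0.5-s interruptions closed). The
analyzer keeps reporting the last expired sample during a hold, so the
plateau onset *is* the final pre-hold end expiration; the onset is
refined to the first sample attaining the plateau level, which is exact
for noiseless traces and accurate to a few samples under realistic
noise. No markers are produced inside a hold; the hold's accumulated
exchange appears in the first recovery breath, and ToB for the
hold-spanning breath includes the hold, consistent with the marker-gap
definition.

Breaths with ΔPCO₂ below 1 mmHg are treated as shallow-breath artifacts
and excluded (logged); the threshold is configurable.

## Delay correction

The analyzer transport delay is estimated as the lag maximizing the
normalized cross-correlation between the breath-band-filtered
(0.1–1 Hz, zero-phase Butterworth) and sign-flipped PCO₂ channel and the
respiration reference filtered the same way. Because the capnogram
waveform is asymmetric, the estimate carries an intrinsic phase offset
of a few tenths of a second relative to "marker-perfect" alignment; an
added transport delay shifts the estimate by exactly that delay, which
is what matters downstream. The search window is ±`max_lag_s` (default
10 s); internally twice that window is scanned so an out-of-range
optimum is recognized, clipped to the boundary, and flagged rather than
silently aliased.

## Interpolation across holds

Metrics exist only at breath timestamps. They are resampled to a
uniform grid (default 0.5 s for Doppler coupling, the repetition time
for BOLD coupling) by linear interpolation; inside a hold the values lie
on the chord between the last pre-hold and first post-hold breath, the
interpolation rule for gas parameters across hold periods. Linear was
chosen because "the values measured immediately before and after" define
exactly a chord; whether the original analyses correlated on the breath
grid or a resampled grid is not documented, and we resample (the choice
is configurable through `grid_dt_s`).

# Wavelet transform coherence

The Morlet mother wavelet with ω₀ = 6 is used on a dyadic grid of 12
scales per octave covering Fourier periods 4–256 s (0.004–0.25 Hz),
`period = scale · 4π/(ω₀ + √(2+ω₀²))`. Squared coherence is

$$R^2(s,t) = \frac{|S(W_{xy}/s)|^2}{S(|W_x|^2/s)\,S(|W_y|^2/s)},$$

with smoothing `S` a Gaussian in time of width proportional to scale
followed by a 0.6-octave boxcar across scale, so `R²` behaves as a
localized correlation coefficient in time–frequency space. The phase of
the smoothed cross-spectrum uses the convention that positive phase
means the first series leads. The cone of influence marks, per time
point, the longest period whose e-folding time fits inside the record
(`period ≤ fourier_factor · d/√2` at distance `d` from the nearer edge).

Significance is estimated by Monte Carlo: AR(1) coefficients are fitted
to both inputs by lag-1 autocorrelation (clipped to 0.99 with a warning
if non-stationary), surrogate pairs are drawn — both series randomized,
since preserving one observed series would test a different null — and
the per-scale 95th percentile of off-cone coherence pooled over time and
surrogates (default 300, seeded) is the threshold. Calibration holds by
construction: on independent AR(1) pairs ~5% of off-cone points exceed
the threshold. Empirically the thresholds are almost invariant to the
AR coefficient — the normalized coherence null is close to pivotal — so
the red-noise fit mainly guards against gross spectral mismatch.

## Time-averaged coherence (TAC)

Per scale and per phase-lag quadrant (half-open: 0±π/2 means phase ∈
(−π/2, π/2]; the four quadrants are 0+π/2, 0−π/2, π−π/2, π+π/2), TAC is
the sum of significant coherence over off-cone points in the quadrant,
normalized by the *maximum possible* coherence outside the cone — read
as the count of qualifying points, each at coherence one. The
alternative reading (normalizing by the summed threshold values) is
available via `normalization = "threshold_sum"`. With a shared
denominator (`denominator = "shared"`) the four quadrant profiles sum
exactly to the unrestricted profile, a useful partition check; the
default per-quadrant denominator matches the per-range normalization of
the statistic's definition. Band means (default 0.008–0.03 Hz, i.e.
periods 33–125 s, the band where gas–hemodynamics coupling concentrates)
average TAC over in-band scales, excluding scales wholly inside the
cone.

# CVR and vCVR mapping

CVR is the slope of the ordinary least-squares regression of a voxel's
percent BOLD change (mean-normalized, 5th-order-polynomial-detrended —
which passes ≥ 0.01 Hz essentially unattenuated on a 10-min record and
grazes 10–15% attenuation at 0.008 Hz) on the vasoactive regressor.
Cluster-extent correction protects against type I error: null volumes of
Gaussian noise, smoothed to a configured FWHM (default 8 mm; estimating
smoothness from data is method-dependent and deliberately out of scope),
are thresholded at the two-sided voxel p < 0.005, and the (1−α) quantile
of the maximal face-adjacent (6-neighbor) cluster size over 2000
iterations gives the minimum cluster volume at family-wise α < 0.05.
Face adjacency is the most conservative of the common connectivity
conventions. vCVR is the percentage of a region's voxels surviving the
correction — a precision measure of how well the regressor predicts the
regional response. Group maps use voxelwise one-sample or paired
t-tests with Benjamini–Hochberg FDR (the variant chosen where the
correction is named only generically); exact-zero differences yield
t = 0 while zero-variance nonzero differences are flagged degenerate.

# The synthetic-data generator

The generator exists so every stage is testable with known ground truth.
It emulates, with defaults stating the study conditions:

* **Protocol**: 60-s lead-in, six 30-s holds, uniform 60–90 s gaps, plus
  a trailing recovery gap (~10 min total); the exogenous CO₂ arm
  alternates +4/+8 mmHg end-tidal steps with first-order approach
  (τ = 10 s).
* **Gas traces** (50 Hz; the within-breath sampling rate is not
  documented anywhere authoritative, so 50 Hz is assumed and
  configurable): piecewise-smooth trapezoid breaths — fast smoothstep
  transitions, gently sloped plateaus so the extremes fall exactly on
  the markers — with end-tidal plateaus 38/110 mmHg, inspired levels
  2/148 mmHg, breath period 4.5 ± 0.4 s. During holds the trace freezes
  at the last expired values. The first recovery breath carries the
  accumulated exchange: swings grow by 1.0 (O₂) and 0.25 (CO₂) mmHg per
  apneic second — the ~4:1 ratio observed between breath-hold-induced O₂
  and CO₂ swing changes. Recovery is a 12-s exponential for the O₂
  swing (total response ≈ twice the hold duration) and a faster
  biexponential with an undershoot (0.8 relative) for CO₂, expressing
  post-apnea hyperventilation. Breath-to-breath end-tidal jitter is
  correlated across channels (r = 0.75), placing the ΔPO₂–ΔPCO₂
  correlation in the 0.6–0.9 band seen in real sessions; a slow
  random-walk channel drift (0.4/0.5 mmHg per breath) moves inspired and
  expired readings together, contaminating end-tidal levels but not the
  swings; the first recovery breaths are prolonged by up to 50%
  (deep slow post-apnea breaths). Additive Gaussian sample noise
  defaults to 0.3 mmHg.
* **Hemodynamics**: a delayed single-exponential impulse response
  (delay 3 s, τ = 10 s; no kernel is documented, so the minimal form
  expressing a delayed, dispersed flow response was chosen; zero
  delay and τ select an identity kernel for exact tests) convolved with
  the z-scored bER drive. Doppler velocity adds a pulsatile cardiac
  waveform with unit per-cycle mean and a coupling gain of 12% per drive
  SD in cohort simulations, giving ~40% hold responses. BOLD voxels get
  slope × convolved regressor plus AR(1) noise (φ = 0.3), with
  ground-truth slopes 3.3%/unit (gray) and 1.5%/unit (white) and 2%
  voxel noise in cohort simulations, matching ~2%/1% gray/white response
  amplitudes. TR defaults to 1.45 s.

Under these conditions the simulated cohorts reproduce, as emergent
properties, the headline orderings: correlation with hemodynamics
descending bER > ΔPO₂ > ToB > ΔPCO₂, and vCVR descending
bER > ToB > P_ET_CO₂. These reproductions are *consistency checks of
the pipeline under the generator's own coupling model*, not independent
evidence about physiology.

What the generator does **not** emulate: realistic pulsatile Doppler
spectra, cardiac/respiratory aliasing in BOLD, motion, baseline
vasomotion unrelated to gas exchange, inter-subject variability in
kernel shape, and measurement dropouts. Passing tests therefore
demonstrate correctness of the computations and internal consistency of
the method, not field performance on clinical recordings.

# Numerical choices and degenerate inputs

* Correlations of exactly ±1 cap Fisher Z at `atanh(1 − 1e−15)` with a
  `saturated` flag, keeping group statistics finite.
* Constant series are errors for correlation (zero variance), empty
  tables with warnings for marker/beat detection, and zero output for
  detrending.
* The CWT zero-pads to the next power of two; smoothing uses linear
  (zero-padded) convolution; edge effects are quarantined by the cone of
  influence rather than corrected.
* Cluster thresholds use a "smallest k with P(max ≥ k) ≤ α" rule, so a
  cluster exactly at threshold size is retained, and α → 1 gives k = 1.
* Seeds: every stochastic routine takes a seed and restores the caller's
  RNG state; child seeds for sub-processes are derived deterministically
  and kept below 2³¹.

# Problem sizes

The test suite and the acceptance script run at desk scale, chosen to
exercise every code path with stable statistics: coherence calibration
on n = 1024 series with 300 surrogates; CVR recovery on 8×8×4 grids with
400 volumes over 20 seeds; orderings over 10 simulated cohorts of one
~10-min session each; cluster calibration on 16³ grids with 500
iterations (2000 is the production default).

# Known limitations

* Marker detection assumes capnogram-like morphology; irregular
  breathing patterns (sighs, Cheyne–Stokes) may need the prominence and
  separation parameters adjusted.
* The delay estimator's sub-breath phase bias is harmless for coupling
  analyses but means absolute lags should not be over-interpreted.
* Cluster-extent calibration takes smoothness as an input rather than
  estimating it from residuals; calibrated thresholds are therefore
  only as good as that input.
* Spatial normalization is out of scope: group maps assume a common
  grid, which synthetic cohorts share by construction.
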