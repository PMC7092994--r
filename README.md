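# cvreact

Cerebrovascular reactivity (CVR) assessment from breath-by-breath
respiratory gas exchange under breath-hold challenge.

Breath holding is the simplest vasoactive stimulus available in the
clinic: repeated ~30-s apneas raise arterial CO₂ and lower arterial O₂,
and the cerebral vasculature dilates in response. CVR is conventionally
quantified by regressing the hemodynamic response on end-tidal CO₂
(P_ET_CO₂), but during a breath hold there is no expirate to measure, and
mild hypoxia and hypercapnia act synergistically. `cvreact` implements an
analysis built around the **breath-by-breath O₂–CO₂ exchange ratio**

    bER = ΔPO₂ / ΔPCO₂,
    ΔPO₂  = inspired PO₂ − expired PO₂,
    ΔPCO₂ = expired PCO₂ − inspired PCO₂,

computed per respiratory cycle from nasal-sampled gas traces, as the
vasoactive regressor, together with the machinery needed to evaluate it:

* **gas** — analyzer delay correction by cross-correlation against a
  respiration-phase reference; end-inspiration / end-expiration marker
  detection on the PCO₂ channel; per-breath ΔPO₂, ΔPCO₂, bER, P_ET_CO₂,
  P_ET_O₂, stimulus index SI = P_ET_CO₂/P_ET_O₂ and time-of-breath
  (ToB); linear interpolation of breath metrics across hold epochs.
* **hemo** — transcranial Doppler preprocessing (median despiking,
  cardiac beat detection, beat-averaged mean velocity, percent change
  against a 30-s baseline) and BOLD preprocessing (mean normalization,
  5th-order polynomial detrending, ROI extraction, initial-volume
  discard).
* **coupling** — Pearson correlation of each gas metric with ΔCBFv /
  ΔBOLD, Fisher Z transforms, and paired group comparisons against bER.
* **wtc** — Morlet (ω₀ = 6) wavelet transform coherence with cone of
  influence, Monte Carlo AR(1) ("red noise") significance thresholds,
  and the **time-averaged coherence** statistic: per scale, the summed
  significant coherence in a phase-lag quadrant normalized by the
  maximum possible coherence outside the cone, with band means over
  0.008–0.03 Hz.
* **cvr** — voxelwise regression of ΔBOLD on a chosen regressor (slope =
  CVR in %BOLD per unit stimulus), Monte Carlo cluster-extent
  calibration (voxel p < 0.005 → family-wise α < 0.05), regional mean
  CVR and **vCVR** (percent of a region's voxels surviving correction),
  and group one-sample / paired t maps with Benjamini–Hochberg FDR.
* **synthetic** — a generator for protocol schedules, gas traces with
  capnogram-like trapezoid breaths and apnea plateaus, pulsatile Doppler
  velocity, and small 4D BOLD datasets with known ground-truth CVR, so
  the full pipeline is testable without any recordings.

Everything is tibble-in / tibble-out and pipe-friendly; result objects
(`wtc_result`, `cvr_maps`) have `tidy()`, `glance()` and `autoplot()`
methods.

## Worked example

Simulate a ten-minute breath-hold session (six 30-s holds, 60–90 s free
breathing), extract breath metrics, and couple them with a simulated
Doppler recording:

```r
library(cvreact)

protocol <- generate_protocol("breath_hold", n_epochs = 6,
                              bh_duration_s = 30, free_range_s = c(60, 90),
                              seed = 1)
gas  <- simulate_gas_traces(protocol, gas_sim_params(seed = 1))
rge  <- gas |> detect_breath_markers(resp = gas$resp) |> compute_rge_metrics()
rge
#> # A tibble: 113 × 8
#>     t_s  dpo2 dpco2   ber petco2 peto2    si tob_s
#>   <dbl> <dbl> <dbl> <dbl>  <dbl> <dbl> <dbl> <dbl>
#> 1  4.14  36.6  37.0 0.989   38.6  111. 0.347 NA
#> 2  8.78  36.4  36.6 0.993   38.3  110. 0.349  4.64
#> 3 12.8   36.0  37.1 0.969   37.7  110. 0.342  4.04
#> 4 18.2   35.5  36.6 0.970   36.6  111. 0.329  5.38
#> # ℹ 109 more rows

cbfv  <- simulate_cbfv(protocol, rge,
                       hemo_sim_params(coupling_gain = 12, noise_sd = 1,
                                       seed = 2))
dcbfv <- cbfv |> despike_median() |>
  (\(v) beat_average(v, detect_cardiac_cycles(v)))()
couple_rge_hemo(rge, dcbfv, source_label = "RMCA")
#> # A tibble: 4 × 7
#>   metric_name source_label     r         p     z n_points saturated
#> 1 ber         RMCA         0.745 1.84e-244 0.963     1377 FALSE
#> 2 dpo2        RMCA         0.566 1.38e-117 0.642     1377 FALSE
#> 3 dpco2       RMCA         0.172 1.44e- 10 0.173     1377 FALSE
#> 4 tob_s       RMCA         0.219 2.08e- 16 0.223     1377 FALSE
```

Each row is the zero-lag Pearson correlation between a breath metric
(resampled to a uniform 0.5-s grid, holds bridged by their chord) and the
percent-change velocity series: bER couples most strongly (r = 0.745),
followed by ΔPO₂, then ToB, then ΔPCO₂ — the ordering the method is
designed to expose. `wtc(pair$a, pair$b, dt = 0.5, seed = 7)` adds the
time-frequency view, and `regress_voxelwise()` /
`cluster_extent_calibrate()` / `regional_summary()` produce CVR and vCVR
maps from a (synthetic or NIfTI) BOLD dataset. `run_pipeline()` chains
all stages and writes every product with a provenance manifest.

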