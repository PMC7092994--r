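mk_trace <- function(v, fs = 25) {
  tibble::new_tibble(
    tibble::tibble(time_s = (seq_along(v) - 1) / fs, velocity = v),
    class = "cbfv_trace", fs = fs)
}

test_that("median despiking removes singleton spikes and keeps smooth signals", {
  v <- mk_trace(c(rep(60, 50), 200, rep(60, 49)))
  out <- despike_median(v, window_s = 0.2)
  expect_equal(out$velocity, rep(60, 100))
  ramp <- mk_trace(seq(40, 80, length.out = 200))
  out2 <- despike_median(ramp, window_s = 0.2)
  expect_equal(out2$velocity[5:195], ramp$velocity[5:195], tolerance = 1e-12)
})

test_that("median despiking equals the brute-force sliding median", {
  set.seed(4)
  x <- rnorm(300, 60, 8)
  v <- mk_trace(x)
  out <- despike_median(v, window_s = 5 / 25)  # window of 5 samples
  oracle <- vapply(3:298, function(i) median(x[(i - 2):(i + 2)]), numeric(1))
  expect_equal(out$velocity[3:298], oracle)
})

test_that("cardiac cycle detection counts a 1 Hz pulse train", {
  fs <- 50
  t <- seq(0, 60, by = 1 / fs)
  v <- mk_trace(60 + 20 * pmax(sin(2 * pi * t), 0)^2, fs = fs)
  beats <- detect_cardiac_cycles(v)
  expect_gte(nrow(beats), 58)
  expect_lte(nrow(beats), 61)
  expect_true(all(beats$t_diastolic_s > beats$t_systolic_s))
  expect_false(any(beats$gap_after))
})

test_that("a flat trace yields no beats and a dropout is flagged, not bridged", {
  expect_warning(b <- detect_cardiac_cycles(mk_trace(rep(60, 500))), "Flat")
  expect_equal(nrow(b), 0)
  fs <- 50
  t <- seq(0, 30, by = 1 / fs)
  pulse <- 60 + 20 * pmax(sin(2 * pi * t), 0)^2
  pulse[t > 14.2 & t < 15.8] <- 60   # one missing beat
  beats <- detect_cardiac_cycles(mk_trace(pulse, fs = fs))
  expect_equal(sum(beats$gap_after), 1)
})

test_that("beat averaging recovers the envelope of a modulated pulse", {
  p <- std_protocol(1)
  drive <- tibble::tibble(time_s = c(0, 100, 100.01, 200, 200.01, 700),
                          value = c(0, 0, 1, 1, 0, 0))
  # 60 bpm at fs 25 makes each cardiac cycle an exact 25 samples, so the
  # per-cycle pulse average is exact
  v <- simulate_cbfv(p, drive,
                     hemo_sim_params(coupling_gain = 40, response_delay_s = 0,
                                     dispersion_tau_s = 0, noise_sd = 0),
                     heart_rate_bpm = 60, drive_scale = "none")
  beats <- detect_cardiac_cycles(v)
  h <- beat_average(v, beats)
  plateau <- h$value[h$time_s > 120 & h$time_s < 180]
  expect_equal(mean(plateau), 40, tolerance = 0.01)
  expect_lt(max(abs(plateau - 40)), 1)
  baselineish <- h$value[h$time_s > 400]
  expect_lt(max(abs(baselineish)), 1)
})

test_that("zero coupling gain gives an identically zero percent-change series", {
  p <- std_protocol(1)
  r <- default_rge()
  v <- simulate_cbfv(p, r, hemo_sim_params(coupling_gain = 0, noise_sd = 0),
                     heart_rate_bpm = 60)
  h <- beat_average(v, detect_cardiac_cycles(v))
  expect_lt(max(abs(h$value)), 1e-8)
})

test_that("artifact spans exclude overlapping cycles", {
  fs <- 50
  t <- seq(0, 30, by = 1 / fs)
  v <- mk_trace(60 + 20 * pmax(sin(2 * pi * t), 0)^2, fs = fs)
  beats <- detect_cardiac_cycles(v)
  h_all <- beat_average(v, beats, baseline_window_s = c(0, 10))
  h_cut <- beat_average(v, beats, artifact_spans = cbind(12, 18),
                        baseline_window_s = c(0, 10))
  expect_lt(nrow(h_cut), nrow(h_all))
  expect_false(any(h_cut$time_s > 12.5 & h_cut$time_s < 17.5))
})

test_that("percent change matches hand arithmetic and is scale invariant", {
  s <- tibble::tibble(time_s = 0:59, value = c(rep(60, 30), rep(84, 30)))
  out <- percent_change(s, baseline_window_s = c(0, 29))
  expect_equal(out$value[60], 40)
  expect_equal(out$value[1], 0)
  const <- percent_change(tibble::tibble(time_s = 0:59, value = 60))
  expect_true(all(const$value == 0))
  s2 <- s; s2$value <- s2$value * 2.7
  expect_equal(percent_change(s2, c(0, 29))$value, out$value, tolerance = 1e-12)
  expect_error(percent_change(tibble::tibble(time_s = 0:59, value = -1)),
               class = "cvreact_bad_baseline")
})

test_that("polynomial detrending removes drift and keeps signal", {
  n <- 414  # ten minutes at TR 1.45
  tt <- seq_len(n)
  drift <- 2e-12 * (tt - n / 2)^5 + 1e-6 * (tt - n / 2)^3 + 0.01 * tt
  y <- 1000 + drift
  r <- detrend_bold(y, order = 5)
  expect_lt(max(abs(r)), 1e-6 * max(abs(100 * y / mean(y))))
  # order 0 is mean removal of the percent series
  y2 <- 1000 + rnorm(n, 0, 5)
  pct <- 100 * y2 / mean(y2)
  expect_equal(detrend_bold(y2, order = 0), pct - mean(pct))
  # a 0.02 Hz oscillation survives within 5 percent
  t_s <- (tt - 1) * 1.45
  y3 <- 1000 + 20 * sin(2 * pi * 0.02 * t_s) + drift
  r3 <- detrend_bold(y3, order = 5)
  fit <- lm(r3 ~ sin(2 * pi * 0.02 * t_s) + cos(2 * pi * 0.02 * t_s))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_equal(amp, 100 * 20 / 1000, tolerance = 0.05)
  expect_equal(detrend_bold(rep(5, 50)), numeric(50))
})

test_that("frequencies at or above 0.008 Hz survive detrending", {
  n <- 414; t_s <- (seq_len(n) - 1) * 1.45
  atten <- vapply(c(0.008, 0.015, 0.05), function(f) {
    y <- 1000 + 10 * sin(2 * pi * f * t_s)
    r <- detrend_bold(y, order = 5)
    fit <- lm(r ~ sin(2 * pi * f * t_s) + cos(2 * pi * f * t_s))
    1 - sqrt(sum(coef(fit)[2:3]^2))
  }, numeric(1))
  # the quintic basis grazes the slowest band edge; attenuation crosses
  # below 10% just above 0.008 Hz on a ten-minute record
  expect_lt(atten[1], 0.15)
  expect_lt(atten[2], 0.10)
  expect_lt(atten[3], 0.02)
})

test_that("ROI extraction averages detrended series per parcellation label", {
  p <- generate_protocol("breath_hold", 2, 30, c(60, 60), seed = 1)
  tv <- seq(0, 250, by = 1.45)
  reg <- tibble::tibble(time_s = tv, value = sin(2 * pi * tv / 100))
  bd <- simulate_bold(p, reg, truth_cvr = 2,
                      hemo_sim_params(response_delay_s = 0,
                                      dispersion_tau_s = 0, noise_sd = 0),
                      grid = c(4, 4, 2), tr_s = 1.45, n_volumes = 150)
  rois <- extract_roi(bd, c("LGM", "RWM"))
  # all voxels share one series, so each ROI mean equals that series
  expect_equal(rois$LGM$value, rois$RWM$value, tolerance = 1e-9)
  one <- detrend_bold(bd$data[1, 1, 1, ], order = 5)
  expect_equal(rois$LGM$value, one, tolerance = 1e-9)
  expect_error(extract_roi(bd, 99), class = "cvreact_empty_label")
})

test_that("initial volumes are discarded once, at read time", {
  p <- generate_protocol("breath_hold", 1, 30, c(60, 60), seed = 1)
  reg <- tibble::tibble(time_s = c(0, 160), value = c(0, 0))
  bd <- simulate_bold(p, reg, 0, hemo_sim_params(noise_sd = 1, seed = 2),
                      grid = c(3, 3, 2), tr_s = 1.45, n_volumes = 100)
  bd2 <- discard_initial_volumes(bd, 12)
  expect_equal(dim(bd2$data)[4], 88)
  expect_equal(bd2$data[, , , 1], bd$data[, , , 13])
})
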