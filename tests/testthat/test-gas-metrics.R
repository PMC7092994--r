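test_that("a known analyzer delay is recovered by cross-correlation", {
  g <- default_gas()
  fs <- attr(g, "fs")
  # the asymmetric capnogram waveform carries a small intrinsic phase
  # offset against the respiration reference; an added transport delay
  # must shift the estimate by exactly that delay
  base <- correct_technical_delay(g, reference = g$resp, max_lag_s = 10)
  expect_lt(abs(base$lag_s), 0.5)
  sh <- round(2 * fs)
  g2 <- g
  n <- nrow(g)
  g2$po2 <- c(rep(g$po2[1], sh), g$po2[1:(n - sh)])
  g2$pco2 <- c(rep(g$pco2[1], sh), g$pco2[1:(n - sh)])
  res <- correct_technical_delay(g2, reference = g2$resp, max_lag_s = 10)
  expect_equal(res$lag_s - base$lag_s, 2, tolerance = 2 / fs + 1e-9)
  expect_equal(res$lag_s, 2, tolerance = 0.5)
  expect_false(res$clipped)
  # after the shift the traces realign with the delayed original
  k <- round(res$lag_s * fs)
  expect_lt(max(abs(res$gas$pco2 - g2$pco2[seq_len(nrow(res$gas)) + k])), 1e-9)
})

test_that("a delay beyond the search window is clipped and flagged", {
  # a single transient gives a localized cross-correlation peak at the
  # true 12-s delay, beyond the 10-s search window: the estimate is
  # clipped to the boundary and flagged
  fs <- 10
  n <- 3000
  tt <- (seq_len(n) - 1) / fs
  bump <- function(center) 10 * exp(-(tt - center)^2 / (2 * 2^2))
  g <- cvreact:::new_gas_traces(
    tibble::tibble(time_s = tt,
                   po2 = 110 - bump(112),
                   pco2 = 38 + bump(112),      # expiratory event, 12 s late
                   resp = -bump(100)),         # expiration deflects negative
    fs = fs)
  res <- correct_technical_delay(g, reference = g$resp, max_lag_s = 10)
  expect_true(res$clipped)
  expect_equal(abs(res$lag_s), 10, tolerance = 1e-9)
})

test_that("a flat respiration reference is refused", {
  g <- default_gas()
  expect_error(correct_technical_delay(g, reference = rep(1, nrow(g))),
               class = "cvreact_flat_reference")
})

test_that("breath markers land on the generator's ground truth", {
  g <- noiseless_gas()
  b <- detect_breath_markers(g, resp = g$resp)
  tr <- attr(g, "truth")
  dt <- 1 / attr(g, "fs")
  # match detected to truth; the final partial breath may be lost
  expect_gte(nrow(b), nrow(tr) - 1)
  err_exp <- vapply(b$t_end_exp_s,
                    function(t) min(abs(tr$t_end_exp_s - t)), numeric(1))
  err_insp <- vapply(b$t_end_insp_s,
                     function(t) min(abs(tr$t_end_insp_s - t)), numeric(1))
  expect_lte(max(err_exp), 2 * dt + 1e-9)
  expect_lte(max(err_insp), 2 * dt + 1e-9)
})

test_that("a constant trace yields an empty breath table with a warning", {
  g <- cvreact:::new_gas_traces(
    tibble::tibble(time_s = seq(0, 60, by = 0.02), po2 = 110, pco2 = 40,
                   resp = 0), fs = 50)
  expect_warning(b <- detect_breath_markers(g), "no oscillation")
  expect_equal(nrow(b), 0)
})

test_that("holds produce no markers inside and a detected first recovery breath", {
  g <- noiseless_gas()
  p <- attr(g, "protocol")
  b <- detect_breath_markers(g, resp = g$resp)
  tr <- attr(g, "truth")
  holds <- p[p$label == "breath_hold", ]
  for (i in seq_len(nrow(holds))) {
    a <- holds$onset_s[i]; e <- a + holds$duration_s[i]
    expect_false(any(b$t_end_exp_s > a + 0.1 & b$t_end_exp_s < e - 0.1))
    first_truth <- tr$t_end_exp_s[tr$t_end_exp_s > e][1]
    expect_true(any(abs(b$t_end_exp_s - first_truth) < 0.1))
  }
})

test_that("bER arithmetic reproduces hand-computed values", {
  breaths <- tibble::tibble(
    t_end_insp_s = c(8, 12, 16), t_end_exp_s = c(10, 14, 18),
    inspired_po2 = c(148, 148, 110), expired_po2 = c(105.3, 143, 105),
    inspired_pco2 = c(2, 2, 2), expired_pco2 = c(41.7, 7, 2.5))
  out <- suppressMessages(compute_rge_metrics(breaths))
  # swings 42.7 / 39.7 give the printed-style ratio 1.0756
  expect_equal(out$ber[1], 42.7 / 39.7, tolerance = 1e-12)
  expect_equal(round(out$ber[1], 1), 1.1)
  expect_equal(out$tob_s[2], 4)
  expect_true(is.na(out$tob_s[1]))
  # the 0.5-mmHg CO2 swing is excluded as a shallow-breath artifact
  expect_equal(nrow(out), 2)
  expect_message(compute_rge_metrics(breaths), "shallow-breath")
  # equal swings give unit bER
  eq <- compute_rge_metrics(tibble::tibble(
    t_end_insp_s = c(1, 5), t_end_exp_s = c(3, 7),
    inspired_po2 = 150, expired_po2 = 145,
    inspired_pco2 = 0, expired_pco2 = 5))
  expect_equal(eq$ber, c(1, 1))
  # invariant: ber * dpco2 == dpo2 to machine precision
  expect_equal(out$ber * out$dpco2, out$dpo2, tolerance = 1e-14)
})

test_that("bER is invariant to rescaling both swings", {
  tr <- attr(noiseless_gas(), "truth")
  scaled <- tr
  c0 <- 1.7
  scaled$expired_po2 <- tr$inspired_po2 - c0 * (tr$inspired_po2 - tr$expired_po2)
  scaled$expired_pco2 <- tr$inspired_pco2 + c0 * (tr$expired_pco2 - tr$inspired_pco2)
  r1 <- suppressMessages(compute_rge_metrics(tr))
  r2 <- suppressMessages(compute_rge_metrics(scaled))
  expect_equal(r1$ber, r2$ber, tolerance = 1e-12)
})

test_that("swings are non-negative on physiologically valid breaths", {
  r <- default_rge()
  expect_true(all(r$dpo2 >= 0))
  expect_true(all(r$dpco2 >= 0))
  expect_true(all(r$si > 0 & r$si <= 1))
})

test_that("time-of-breath accounting closes over the record", {
  r <- default_rge()
  span <- max(r$t_s) - min(r$t_s)
  expect_equal(sum(r$tob_s, na.rm = TRUE), span,
               tolerance = attr(default_gas(), "params")$breath_period_mean / span)
})

test_that("interpolation bridges holds along the chord", {
  rge <- tibble::tibble(t_s = c(0, 10, 40, 50), ber = c(1, 1, 2, 2))
  out <- interpolate_over_breath_holds(rge, grid_dt_s = 0.5)
  expect_equal(out$ber[out$time_s == 25], 1.5)
  # knots are preserved exactly
  expect_equal(out$ber[out$time_s == 10], 1)
  expect_equal(out$ber[out$time_s == 40], 2)
  # without holds this is plain linear interpolation
  plain <- approx(rge$t_s, rge$ber, xout = out$time_s)$y
  expect_equal(out$ber, plain)
})

test_that("an unflanked hold raises an error naming the epoch", {
  rge <- tibble::tibble(t_s = c(100, 105, 110), ber = 1)
  p <- std_protocol(1)  # first hold starts at 60 s, before any breath
  expect_error(interpolate_over_breath_holds(rge, protocol = p),
               class = "cvreact_unflanked_hold")
})

test_that("the simulate-detect-compute round trip recovers configured swings", {
  g <- noiseless_gas()
  prm <- attr(g, "params")
  b <- detect_breath_markers(g, resp = g$resp)
  r <- suppressMessages(compute_rge_metrics(b))
  base <- r[r$t_s < 60, ]  # pre-challenge baseline
  target_dpo2 <- prm$inspired_po2 - prm$baseline_peto2
  target_dpco2 <- prm$baseline_petco2 - prm$inspired_pco2
  expect_equal(mean(base$dpo2), target_dpo2, tolerance = 0.02)
  expect_equal(mean(base$dpco2), target_dpco2, tolerance = 0.02)
  expect_equal(mean(base$ber), target_dpo2 / target_dpco2, tolerance = 0.02)
})
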