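#' Correct the technical delay of gas traces against a respiration reference
#'
#' Gas analyzers report PO2/PCO2 with a transport delay relative to the
#' respiration they sample. The delay is estimated as the lag maximizing
#' the normalized cross-correlation between the breath-band-filtered PCO2
#' channel and a respiration-phase reference, searched within
#' `+/- max_lag_s`, and the traces are advanced by that lag (ends trimmed,
#' never wrapped).
#'
#' The expired-CO2 upstroke is an inverted copy of the respiration phase
#' (expiration drives PCO2 up while the reference convention is positive
#' during inspiration), so the filtered PCO2 is negated before
#' cross-correlating.
#'
#' @param gas a `gas_traces` tibble (columns `time_s`, `po2`, `pco2`, and
#'   optionally `resp`), with attribute `fs`.
#' @param reference numeric respiration-phase series on the same grid as
#'   `gas` (defaults to the trace's own `resp` channel).
#' @param max_lag_s search half-width, seconds.
#' @param band_hz passband of the breath-band filter used before
#'   cross-correlation, Hz.
#' @return list with elements `gas` (shifted traces), `lag_s` (the
#'   estimated delay) and `clipped` (`TRUE` when the estimate hit the
#'   search boundary and should not be trusted).
#' @export
correct_technical_delay <- function(gas, reference = gas$resp,
                                    max_lag_s = 10, band_hz = c(0.1, 1)) {
  fs <- attr(gas, "fs")
  stopifnot(!is.null(fs))
  assert_scalar_number(max_lag_s, "max_lag_s", lower = 0, strict_lower = TRUE)
  if (length(reference) != nrow(gas)) {
    stop_cvreact("`reference` must share the gas trace's sample grid.")
  }
  if (stats::sd(reference) == 0) {
    stop_cvreact("no respiratory phase information: reference has zero variance.",
                 "cvreact_flat_reference")
  }

  nyq <- fs / 2
  bf <- signal::butter(2, pmin(band_hz / nyq, 0.99), type = "pass")
  sig <- -as.numeric(signal::filtfilt(bf, gas$pco2 - mean(gas$pco2)))
  # the same zero-phase filter on both sides keeps the correlation peak
  # centered on the true transport delay
  ref <- as.numeric(signal::filtfilt(bf, reference - mean(reference)))

  max_lag <- round(max_lag_s * fs)
  # search twice the requested window so an out-of-range optimum can be
  # recognized, clipped to the boundary, and flagged
  cc <- stats::ccf(sig, ref, lag.max = 2L * max_lag, plot = FALSE,
                   demean = TRUE, type = "correlation")
  # ccf lag k correlates sig_{t+k} with ref_t: a positive analyzer delay
  # (gas events later than reference) peaks at positive k
  k <- cc$lag[which.max(cc$acf)]
  clipped <- abs(k) > max_lag
  k <- max(-max_lag, min(max_lag, k))
  lag_s <- k / fs

  shift <- as.integer(k)
  n <- nrow(gas)
  if (shift == 0L) {
    out <- gas
  } else {
    # new[i] = old[i + shift]; rows without a source sample are trimmed
    idx_new <- seq(max(1L, 1L - shift), min(n, n - shift))
    out <- gas[idx_new, ]
    out$po2 <- gas$po2[idx_new + shift]
    out$pco2 <- gas$pco2[idx_new + shift]
  }
  out <- new_gas_traces(out, fs = fs, protocol = attr(gas, "protocol"),
                        params = attr(gas, "params"),
                        truth = attr(gas, "truth"))
  list(gas = out, lag_s = lag_s, clipped = clipped)
}

#' Detect end-inspiration and end-expiration markers on gas traces
#'
#' Marks each breath on the PCO2 channel: end expiration as the local
#' maximum terminating the expiratory plateau, end inspiration as the
#' preceding local minimum. PO2 values are read at the PCO2-derived
#' timestamps so both channels share one time base. Apneic (breath-hold)
#' stretches, recognized as near-flat runs longer than `min_apnea_s`,
#' produce no breaths; the last pre-apnea end expiration is placed at the
#' plateau onset. When a respiration-phase series is supplied, markers
#' falling in the wrong phase are rejected.
#'
#' @param gas a `gas_traces` tibble.
#' @param resp optional respiration-phase reference (positive during
#'   inspiration, negative during expiration) on the same grid.
#' @param min_prominence_frac peak prominence threshold as a fraction of
#'   the interquartile range of the PCO2 trace.
#' @param min_separation_s minimum spacing between end-expiration
#'   markers, seconds.
#' @param min_apnea_s minimum duration of a flat run treated as apnea,
#'   seconds.
#' @return A `breath_table` tibble: one row per breath with
#'   `t_end_insp_s`, `t_end_exp_s`, `inspired_po2`, `expired_po2`,
#'   `inspired_pco2`, `expired_pco2`.
#' @export
detect_breath_markers <- function(gas, resp = NULL,
                                  min_prominence_frac = 0.25,
                                  min_separation_s = 1.5,
                                  min_apnea_s = 10) {
  fs <- attr(gas, "fs")
  stopifnot(!is.null(fs))
  x <- gas$pco2
  n <- length(x)
  empty <- tibble::tibble(t_end_insp_s = numeric(0), t_end_exp_s = numeric(0),
                          inspired_po2 = numeric(0), expired_po2 = numeric(0),
                          inspired_pco2 = numeric(0), expired_pco2 = numeric(0))
  class(empty) <- c("breath_table", class(empty))
  iqr <- stats::IQR(x)
  if (iqr < .Machine$double.eps^0.5) {
    warn("Gas trace shows no oscillation; returning an empty breath table.")
    return(empty)
  }

  # light smoothing for peak work; heavier smoothing for the slope-based
  # apnea detector, whose flat-run test must not trip on sample noise
  k <- max(3L, round(0.25 * fs))
  xs <- moving_average(x, k)
  k_ap <- max(5L, round(1.0 * fs))
  slope <- moving_average(c(0, diff(moving_average(x, k_ap))) * fs,
                          max(3L, round(0.5 * fs)))
  noise_guess <- stats::mad(diff(x)) / sqrt(2)
  flat_tol <- 0.3
  flat <- abs(slope) < flat_tol
  # close sub-0.5 s interruptions so sample noise cannot split a hold
  r0 <- rle(flat)
  gap <- !r0$values & r0$lengths < round(0.5 * fs)
  gap[c(1L, length(gap))] <- FALSE
  r0$values[gap] <- TRUE
  flat <- inverse.rle(r0)
  runs <- rle(flat)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  apnea <- runs$values & runs$lengths >= min_apnea_s * fs
  apnea_runs <- cbind(run_start[apnea], run_end[apnea])
  # a buffer absorbs the boundary blur of the smoothed slope estimate
  buf <- round(1.5 * fs)
  in_apnea <- logical(n)
  for (r in seq_len(nrow(apnea_runs))) {
    in_apnea[max(1L, apnea_runs[r, 1] - buf):
               min(n, apnea_runs[r, 2] + buf)] <- TRUE
  }

  # refine each apnea onset to the plateau edge: the first sample of the
  # search window attaining the plateau maximum (up to the within-run
  # noise level), since expiration rises monotonically into the plateau
  apnea_onsets <- integer(0)
  half_w <- round(3 * fs)
  for (r in seq_len(nrow(apnea_runs))) {
    run <- apnea_runs[r, 1]:apnea_runs[r, 2]
    noise_run <- stats::mad(diff(x[run])) / sqrt(2)
    w <- max(1L, apnea_runs[r, 1] - half_w):
      min(apnea_runs[r, 2], apnea_runs[r, 1] + half_w)
    m <- max(x[w])
    i <- w[which(x[w] >= m - max(3 * noise_run, 1e-9))[1]]
    apnea_onsets <- c(apnea_onsets, i)
    if (i < apnea_runs[r, 1]) in_apnea[i:apnea_runs[r, 1]] <- TRUE
  }

  peaks <- find_peaks(xs, min_prominence = min_prominence_frac * iqr,
                      min_separation = round(min_separation_s * fs))
  # snap smoothed peaks back onto the raw trace
  peaks <- vapply(peaks, function(i) {
    w <- max(1L, i - k):min(n, i + k)
    w[which.max(x[w])]
  }, integer(1))
  peaks <- peaks[!in_apnea[peaks]]
  # apnea onsets are end-expiration markers too; they take precedence over
  # any ordinary peak detected within one breath of them
  sep <- round(min_separation_s * fs)
  peaks <- peaks[!vapply(peaks, function(i) any(abs(i - apnea_onsets) < sep),
                         logical(1))]
  peaks <- sort(unique(c(peaks, apnea_onsets)))

  if (length(peaks) == 0L) {
    warn("No breaths detected; returning an empty breath table.")
    return(empty)
  }

  # end inspiration: minimum between the previous end expiration (or the
  # record start / apnea end) and this end expiration, outside apnea
  insp_idx <- integer(length(peaks))
  for (j in seq_along(peaks)) {
    lo <- if (j == 1L) 1L else peaks[j - 1L] + 1L
    prior_apnea_end <- apnea_runs[apnea_runs[, 2] < peaks[j], 2]
    if (length(prior_apnea_end) > 0) lo <- max(lo, max(prior_apnea_end) + 1L)
    w <- lo:peaks[j]
    w <- w[!in_apnea[w]]
    insp_idx[j] <- if (length(w) > 0) w[which.min(x[w])] else NA_integer_
  }
  keep <- !is.na(insp_idx) & insp_idx < peaks
  peaks <- peaks[keep]; insp_idx <- insp_idx[keep]

  if (!is.null(resp)) {
    if (length(resp) != n) {
      stop_cvreact("`resp` must share the gas trace's sample grid.")
    }
    rs <- moving_average(resp, k)
    thr <- 0.25 * stats::sd(rs)
    # end expiration must not fall mid-inspiration, end inspiration must
    # not fall mid-expiration
    ok <- rs[peaks] < thr & rs[insp_idx] > -thr
    peaks <- peaks[ok]; insp_idx <- insp_idx[ok]
  }

  out <- tibble::tibble(
    t_end_insp_s = gas$time_s[insp_idx],
    t_end_exp_s = gas$time_s[peaks],
    inspired_po2 = gas$po2[insp_idx],
    expired_po2 = gas$po2[peaks],
    inspired_pco2 = gas$pco2[insp_idx],
    expired_pco2 = gas$pco2[peaks]
  )
  class(out) <- c("breath_table", class(out))
  out
}

#' Compute breath-by-breath respiratory gas-exchange metrics
#'
#' From a breath table, derives per breath: the within-breath swings
#' `dpo2` (inspired - expired PO2) and `dpco2` (expired - inspired PCO2),
#' the O2-CO2 exchange ratio `ber = dpo2 / dpco2`, the end-tidal
#' pressures `petco2` / `peto2` read at end expiration, the stimulus
#' index `si = petco2 / peto2`, and the time of breath `tob_s` between
#' consecutive end-expiration markers (undefined, `NA`, for the first
#' breath). Breaths with `dpco2` below `min_dpco2` are shallow-breath
#' artifacts: they are excluded and reported via a message.
#'
#' @param breaths a breath table from [detect_breath_markers()].
#' @param min_dpco2 smallest physiologically valid CO2 swing, mmHg.
#' @return An `rge_series` tibble with columns `t_s` (stamped at end
#'   expiration), `dpo2`, `dpco2`, `ber`, `petco2`, `peto2`, `si`,
#'   `tob_s`.
#' @export
compute_rge_metrics <- function(breaths, min_dpco2 = 1) {
  stopifnot(is.data.frame(breaths))
  out <- tibble::tibble(
    t_s = breaths$t_end_exp_s,
    dpo2 = breaths$inspired_po2 - breaths$expired_po2,
    dpco2 = breaths$expired_pco2 - breaths$inspired_pco2
  )
  bad <- out$dpco2 < min_dpco2
  if (any(bad)) {
    inform(sprintf(
      "Excluding %d breath(s) with dpco2 below %g mmHg as shallow-breath artifacts.",
      sum(bad), min_dpco2))
    out <- out[!bad, , drop = FALSE]
    breaths <- breaths[!bad, , drop = FALSE]
  }
  out$ber <- out$dpo2 / out$dpco2
  out$petco2 <- breaths$expired_pco2
  out$peto2 <- breaths$expired_po2
  out$si <- out$petco2 / out$peto2
  out$tob_s <- c(NA_real_, diff(out$t_s))
  class(out) <- c("rge_series", class(out))
  out
}

#' Resample breath-wise metrics to a uniform grid, bridging breath holds
#'
#' Linearly interpolates each metric of an RGE series from its irregular
#' breath timestamps onto a uniform grid. No breaths occur during a
#' breath hold, so inside hold epochs the resampled values lie on the
#' chord between the last pre-hold and first post-hold breath -- the
#' interpolation rule used for gas parameters across hold periods.
#'
#' @param rge an `rge_series` tibble (or any tibble with a `t_s` column
#'   and numeric metric columns).
#' @param grid_dt_s grid spacing, seconds.
#' @param protocol optional `protocol_schedule`; when supplied, every
#'   breath-hold epoch is checked for a flanking breath on each side and
#'   a missing flank raises an error naming the epoch.
#' @param metrics character vector of columns to resample (default: all
#'   numeric metric columns).
#' @return tibble with `time_s` and one column per metric.
#' @export
interpolate_over_breath_holds <- function(rge, grid_dt_s = 0.5,
                                          protocol = NULL,
                                          metrics = NULL) {
  stopifnot(is.data.frame(rge), "t_s" %in% names(rge))
  if (nrow(rge) < 2L) stop_cvreact("Need at least two breaths to resample.")
  metrics <- metrics %||%
    setdiff(names(rge)[vapply(rge, is.numeric, logical(1))], "t_s")
  if (!is.null(protocol)) {
    ch <- protocol_challenges(protocol)
    ch <- ch[ch$label == "breath_hold", , drop = FALSE]
    for (i in seq_len(nrow(ch))) {
      a <- ch$onset_s[i]; b <- ch$onset_s[i] + ch$duration_s[i]
      if (!any(rge$t_s <= a + 1e-9) || !any(rge$t_s >= b - 1e-9)) {
        stop_cvreact(sprintf(
          "Breath-hold epoch %d (%.0f-%.0f s) has no flanking breath on both sides.",
          i, a, b), "cvreact_unflanked_hold")
      }
    }
  }
  grid <- seq(min(rge$t_s), max(rge$t_s), by = grid_dt_s)
  out <- tibble::tibble(time_s = grid)
  for (m in metrics) {
    keep <- !is.na(rge[[m]])
    if (sum(keep) < 2L) {
      out[[m]] <- NA_real_
      next
    }
    xs <- rge$t_s[keep]
    g <- pmin(pmax(grid, min(xs)), max(xs))
    out[[m]] <- approx(xs, rge[[m]][keep], xout = g, ties = "ordered")$y
  }
  out
}
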