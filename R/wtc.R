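# Morlet continuous wavelet transform and wavelet transform coherence.
#
# The transform follows the standard Morlet (omega0 = 6) formulation on a
# dyadic scale grid; coherence uses scale-dependent Gaussian smoothing in
# time and a 0.6-octave boxcar across scale, so that the squared
# cross-spectrum normalized by the smoothed auto-spectra behaves as a
# localized correlation coefficient in time-frequency space.

morlet_omega0 <- 6
# Fourier period per unit scale for the Morlet wavelet
fourier_factor <- function(omega0 = morlet_omega0) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

# dyadic scale grid covering period_range (seconds)
wtc_scales <- function(dt, n, scales_per_octave = 12,
                       period_range_s = c(4, 256)) {
  ff <- fourier_factor()
  max_period <- n * dt
  hi <- period_range_s[2]
  if (hi > max_period) {
    warn(sprintf(
      "Longest requested period (%g s) exceeds the record (%g s); scales truncated.",
      hi, max_period))
    hi <- max_period
  }
  if (period_range_s[1] < 2 * dt) {
    period_range_s[1] <- 2 * dt
  }
  j_max <- floor(scales_per_octave * log2(hi / period_range_s[1]))
  periods <- period_range_s[1] * 2^(seq(0, j_max) / scales_per_octave)
  list(scales = periods / ff, periods = periods, freqs = 1 / periods)
}

#' Morlet continuous wavelet transform
#'
#' Computes the CWT of a uniformly sampled series with the Morlet mother
#' wavelet (center frequency 6) on a dyadic scale grid. The series is
#' demeaned and zero-padded to the next power of two; the equivalent
#' Fourier period of scale `s` is `s * 4 * pi / (omega0 + sqrt(2 + omega0^2))`.
#'
#' @param x numeric series.
#' @param dt sample spacing, seconds.
#' @param scales_per_octave scale resolution (default 12).
#' @param period_range_s `(lo, hi)` Fourier periods to cover, seconds;
#'   truncated with a warning if `hi` exceeds the record length.
#' @return list with `coef` (complex scale x time matrix), `scales`,
#'   `periods`, `freqs`, `times`, `coi` (per-time maximum valid period,
#'   seconds).
#' @export
cwt_morlet <- function(x, dt, scales_per_octave = 12,
                       period_range_s = c(4, 256)) {
  n <- length(x)
  stopifnot(n >= 4L, dt > 0)
  sc <- wtc_scales(dt, n, scales_per_octave, period_range_s)
  x <- x - mean(x)
  npad <- stats::nextn(n, 2)
  xp <- c(x, numeric(npad - n))
  xh <- fft(xp)
  k <- seq_len(npad) - 1L
  omega <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / (npad * dt)

  w0 <- morlet_omega0
  coef <- matrix(0i, nrow = length(sc$scales), ncol = n)
  for (j in seq_along(sc$scales)) {
    s <- sc$scales[j]
    psi <- sqrt(2 * pi * s / dt) * pi^(-1 / 4) *
      exp(-((s * omega - w0)^2) / 2) * (omega > 0)
    w <- fft(xh * psi, inverse = TRUE) / npad
    coef[j, ] <- w[seq_len(n)]
  }

  times <- (seq_len(n) - 1L) * dt
  dist_edge <- pmin(times, times[n] - times) + dt * 1e-8
  coi <- fourier_factor() / sqrt(2) * dist_edge

  list(coef = coef, scales = sc$scales, periods = sc$periods,
       freqs = sc$freqs, times = times, coi = coi)
}

# Gaussian time smoothing (sd = scale, per row) then boxcar across scale
# (0.6 octave), both via linear convolution.
wtc_smooth <- function(m, scales, dt, scales_per_octave) {
  n <- ncol(m)
  pad <- stats::nextn(n + 2L * ceiling(4 * max(scales) / dt), 2)
  k <- seq_len(pad) - 1L
  omega <- 2 * pi * ifelse(k <= pad / 2, k, k - pad) / (pad * dt)
  is_cplx <- is.complex(m)
  mp <- matrix(if (is_cplx) 0i else 0, nrow = pad, ncol = nrow(m))
  mp[seq_len(n), ] <- t(m)
  mh <- mvfft(mp)
  filt <- exp(-0.5 * outer(omega, scales)^2)
  sm <- mvfft(mh * filt, inverse = TRUE) / pad
  sm <- t(sm[seq_len(n), , drop = FALSE])
  if (!is_cplx) sm <- Re(sm)

  win <- max(1L, round(0.6 * scales_per_octave))
  if (win %% 2L == 0L) win <- win + 1L
  if (win > 1L && nrow(sm) > 1L) {
    h <- (win - 1L) %/% 2L
    idx <- function(i) pmin(pmax(i, 1L), nrow(sm))
    acc <- sm * 0
    for (o in -h:h) acc <- acc + sm[idx(seq_len(nrow(sm)) + o), , drop = FALSE]
    sm <- acc / win
  }
  sm
}

#' Wavelet transform coherence between two series
#'
#' Squared coherence
#' `R2 = |S(Wxy / s)|^2 / (S(|Wx|^2 / s) * S(|Wy|^2 / s))` with the
#' smoothing operator `S` of [wtc_smooth] (Gaussian in time with width
#' proportional to scale, then a 0.6-octave boxcar across scale), plus
#' the cross-wavelet phase `arg S(Wxy / s)`. Positive phase means `x`
#' leads `y`.
#'
#' @inheritParams cwt_morlet
#' @param y second series, same grid as `x`.
#' @return A `wtc_result`: list with `times`, `scales`, `periods`,
#'   `freqs`, `coherence`, `phase` (scale x time matrices), `coi`
#'   (per-time maximum valid period, seconds), `sig_threshold` (`NULL`
#'   until [montecarlo_threshold()] is attached) and `params`.
#' @export
wavelet_coherence <- function(x, y, dt, scales_per_octave = 12,
                              period_range_s = c(4, 256)) {
  if (length(x) != length(y)) {
    stop_cvreact("Series must have equal length.", "cvreact_length_mismatch")
  }
  wx <- cwt_morlet(x, dt, scales_per_octave, period_range_s)
  wy <- cwt_morlet(y, dt, scales_per_octave, period_range_s)
  inv_s <- 1 / wx$scales

  sxx <- wtc_smooth(Mod(wx$coef)^2 * inv_s, wx$scales, dt, scales_per_octave)
  syy <- wtc_smooth(Mod(wy$coef)^2 * inv_s, wx$scales, dt, scales_per_octave)
  sxy <- wtc_smooth(wx$coef * Conj(wy$coef) * inv_s, wx$scales, dt,
                    scales_per_octave)

  coh <- Mod(sxy)^2 / pmax(sxx * syy, .Machine$double.xmin)
  coh <- pmin(pmax(coh, 0), 1)
  phase <- Arg(sxy)

  structure(list(times = wx$times, scales = wx$scales, periods = wx$periods,
                 freqs = wx$freqs, coherence = coh, phase = phase,
                 coi = wx$coi, sig_threshold = NULL,
                 params = list(dt = dt, scales_per_octave = scales_per_octave,
                               period_range_s = period_range_s)),
            class = "wtc_result")
}

#' @export
print.wtc_result <- function(x, ...) {
  cat(sprintf(
    "<wtc_result: %d scales (periods %.3g-%.3g s) x %d times, dt %g s%s>\n",
    length(x$scales), min(x$periods), max(x$periods), length(x$times),
    x$params$dt,
    if (is.null(x$sig_threshold)) "" else ", 95% red-noise threshold attached"))
  invisible(x)
}

# logical matrix: TRUE where the scale's period is shorter than the COI
# period (i.e. the estimate is outside the cone of influence and valid)
off_coi_mask <- function(wtc) {
  outer(wtc$periods, wtc$coi, FUN = "<")
}

# lag-1 autocorrelation, clipped for surrogate stability
ar1_coefficient <- function(x) {
  x <- x - mean(x)
  phi <- sum(x[-1] * x[-length(x)]) / sum(x^2)
  if (abs(phi) >= 1) {
    warn("AR(1) fit outside the unit circle; clipping to 0.99.")
    phi <- sign(phi) * 0.99
  }
  phi
}

#' Monte Carlo red-noise significance threshold for wavelet coherence
#'
#' Fits an AR(1) ("red noise") model to each input series by lag-1
#' autocorrelation, generates `n_surrogates` independent surrogate pairs
#' with those coefficients, computes their wavelet coherence, and takes
#' the 95th percentile (or `1 - alpha` quantile) of the off-COI coherence
#' values pooled over time and surrogates, per scale.
#'
#' @inheritParams wavelet_coherence
#' @param n_surrogates number of surrogate pairs (>= 100).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed for the surrogate draws.
#' @return numeric vector of per-scale coherence thresholds in `(0, 1)`.
#' @export
montecarlo_threshold <- function(x, y, dt, n_surrogates = 300,
                                 scales_per_octave = 12,
                                 period_range_s = c(4, 256),
                                 alpha = 0.05, seed = 1L) {
  if (n_surrogates < 100) {
    stop_cvreact("Need at least 100 surrogates.", "cvreact_invalid_parameter")
  }
  n <- length(x)
  phi_x <- ar1_coefficient(x)
  phi_y <- ar1_coefficient(y)
  template <- suppressWarnings(
    wtc_scales(dt, n, scales_per_octave, period_range_s))
  n_scales <- length(template$scales)
  pooled <- vector("list", n_surrogates)
  with_seed(seed, {
    for (b in seq_len(n_surrogates)) {
      xs <- as.numeric(stats::arima.sim(list(ar = max(abs(phi_x), 1e-8) *
                                               sign(phi_x + 1e-12)), n = n))
      ys <- as.numeric(stats::arima.sim(list(ar = max(abs(phi_y), 1e-8) *
                                               sign(phi_y + 1e-12)), n = n))
      w <- suppressWarnings(
        wavelet_coherence(xs, ys, dt, scales_per_octave, period_range_s))
      off <- off_coi_mask(w)
      cc <- w$coherence
      cc[!off] <- NA_real_
      pooled[[b]] <- cc
    }
  })
  stacked <- array(unlist(pooled), dim = c(n_scales, n, n_surrogates))
  thr <- apply(stacked, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else unname(quantile(v, 1 - alpha))
  })
  pmin(pmax(thr, .Machine$double.eps), 1 - .Machine$double.eps)
}

#' Wavelet coherence with attached red-noise significance
#'
#' Convenience wrapper: [wavelet_coherence()] plus
#' [montecarlo_threshold()] stored in `sig_threshold`.
#'
#' @inheritParams montecarlo_threshold
#' @return a `wtc_result` with `sig_threshold` attached.
#' @export
wtc <- function(x, y, dt, n_surrogates = 300, scales_per_octave = 12,
                period_range_s = c(4, 256), alpha = 0.05, seed = 1L) {
  w <- wavelet_coherence(x, y, dt, scales_per_octave, period_range_s)
  w$sig_threshold <- montecarlo_threshold(
    x, y, dt, n_surrogates = n_surrogates,
    scales_per_octave = scales_per_octave,
    period_range_s = period_range_s, alpha = alpha, seed = seed)
  w
}

# phase-quadrant membership, half-open boundaries
phase_in_quadrant <- function(phase, quadrant) {
  switch(quadrant,
         "0+pi/2" = phase > 0 & phase <= pi / 2,
         "0-pi/2" = phase > -pi / 2 & phase <= 0,
         "pi-pi/2" = phase > pi / 2 & phase <= pi,
         "pi+pi/2" = phase > -pi & phase <= -pi / 2,
         "0" = phase > -pi / 2 & phase <= pi / 2,
         "pi" = phase <= -pi / 2 | phase > pi / 2,
         "all" = !is.na(phase),
         stop_cvreact(sprintf("Unknown phase quadrant '%s'.", quadrant)))
}

#' Time-averaged coherence per scale within a phase-lag range
#'
#' For each scale, sums the significant coherence (values exceeding the
#' attached 95% red-noise threshold) over the off-COI time points whose
#' phase falls in the requested range, and normalizes by the maximum
#' possible coherence outside the cone of influence at that scale --
#' i.e. by the count of qualifying points each at coherence one
#' (`normalization = "count"`, the default reading) or by the summed
#' threshold values (`"threshold_sum"`).
#'
#' @param wtc a `wtc_result` with `sig_threshold` attached.
#' @param quadrant one of `"0+pi/2"`, `"0-pi/2"`, `"pi-pi/2"`,
#'   `"pi+pi/2"` (quadrants), `"0"`, `"pi"` (quadrant pairs) or `"all"`.
#' @param denominator `"quadrant"` counts only off-COI points in the
#'   phase range (the per-range normalization); `"shared"` counts all
#'   off-COI points at the scale, so the four quadrant profiles sum to
#'   the unrestricted profile.
#' @param normalization `"count"` or `"threshold_sum"`.
#' @return A `tac_profile` tibble: `period_s`, `freq_hz`, `quadrant`,
#'   `tac`, `n_offcoi`. Scales fully inside the COI have `tac = NA`.
#' @export
time_averaged_coherence <- function(wtc, quadrant = "0",
                                    denominator = c("quadrant", "shared"),
                                    normalization = c("count", "threshold_sum")) {
  denominator <- match.arg(denominator)
  normalization <- match.arg(normalization)
  if (is.null(wtc$sig_threshold)) {
    stop_cvreact("Attach a significance threshold first (see wtc() or montecarlo_threshold()).")
  }
  off <- off_coi_mask(wtc)
  inq <- phase_in_quadrant(wtc$phase, quadrant)
  sig <- sweep(wtc$coherence, 1, wtc$sig_threshold, `>`)
  n_scales <- length(wtc$scales)
  tac <- numeric(n_scales)
  n_off <- integer(n_scales)
  for (j in seq_len(n_scales)) {
    o <- off[j, ]
    n_off[j] <- sum(o)
    sel <- o & inq[j, ]
    num <- sum(wtc$coherence[j, sel & sig[j, ]])
    den <- switch(normalization,
                  count = if (denominator == "quadrant") sum(sel) else sum(o),
                  threshold_sum = wtc$sig_threshold[j] *
                    (if (denominator == "quadrant") sum(sel) else sum(o)))
    tac[j] <- if (n_off[j] == 0L || den == 0) NA_real_ else num / den
  }
  tibble::new_tibble(
    tibble::tibble(period_s = wtc$periods, freq_hz = wtc$freqs,
                   quadrant = quadrant, tac = tac, n_offcoi = n_off),
    class = "tac_profile")
}

#' Mean time-averaged coherence over a frequency band
#'
#' Averages a TAC profile over the scales whose frequency lies in
#' `band_hz` (periods of 33--125 s for the 0.008--0.03 Hz band on the
#' default grid). Scales flagged undefined (fully inside the COI) are
#' excluded.
#'
#' @param tac a `tac_profile` from [time_averaged_coherence()].
#' @param band_hz `(lo, hi)` frequency band, Hz.
#' @return scalar band mean.
#' @export
band_mean_tac <- function(tac, band_hz = c(0.008, 0.03)) {
  sel <- tac$freq_hz >= band_hz[1] & tac$freq_hz <= band_hz[2] &
    is.finite(tac$tac)
  if (!any(sel)) stop_cvreact("No valid scales in the requested band.",
                              "cvreact_empty_band")
  mean(tac$tac[sel])
}
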