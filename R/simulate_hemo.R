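#' Parameters of the simulated hemodynamic response
#'
#' The cerebral response to a vasoactive drive is modelled as a delayed
#' single-exponential impulse response: unit-area kernel
#' `h(t) = exp(-(t - delay)/tau) / tau` for `t >= delay`. The default
#' 3 s delay and 10 s time constant express the observation that the
#' flow response to a breath hold outlasts the hold itself. Setting both
#' `response_delay_s` and `dispersion_tau_s` to zero selects an identity
#' kernel (no temporal blurring), which is convenient for exact recovery
#' tests.
#'
#' @param coupling_gain percent signal change per unit of the (convolved)
#'   drive.
#' @param response_delay_s kernel onset delay, seconds (>= 0).
#' @param dispersion_tau_s exponential time constant, seconds (>= 0; 0
#'   together with zero delay means identity).
#' @param ar1_coef lag-1 autocorrelation of the additive noise, in
#'   `[0, 1)`.
#' @param noise_sd noise standard deviation, percent signal.
#' @param seed integer seed.
#' @return a list of class `hemo_sim_params`.
#' @export
hemo_sim_params <- function(coupling_gain = 40,
                            response_delay_s = 3,
                            dispersion_tau_s = 10,
                            ar1_coef = 0.3,
                            noise_sd = 1,
                            seed = 1L) {
  p <- as.list(environment())
  assert_scalar_number(p$response_delay_s, "response_delay_s", lower = 0)
  assert_scalar_number(p$dispersion_tau_s, "dispersion_tau_s", lower = 0)
  if (abs(p$ar1_coef) >= 1) {
    stop_cvreact("|ar1_coef| must be below 1.", "cvreact_invalid_parameter")
  }
  assert_scalar_number(p$noise_sd, "noise_sd", lower = 0)
  structure(p, class = "hemo_sim_params")
}

#' Convolve a drive with the delayed-exponential hemodynamic kernel
#'
#' Discrete causal convolution with the unit-area kernel described in
#' [hemo_sim_params()]. With zero delay and zero time constant the drive
#' is returned unchanged.
#'
#' @param drive numeric vector, uniformly sampled.
#' @param dt sample spacing, seconds.
#' @param delay_s,tau_s kernel parameters, seconds.
#' @return numeric vector, same length as `drive`.
#' @export
hemo_kernel_convolve <- function(drive, dt, delay_s = 3, tau_s = 10) {
  if (delay_s == 0 && tau_s == 0) return(drive)
  t_k <- seq(0, max(delay_s + 8 * max(tau_s, dt), dt), by = dt)
  h <- if (tau_s == 0) as.numeric(abs(t_k - delay_s) < dt / 2) else {
    ifelse(t_k >= delay_s, exp(-(t_k - delay_s) / tau_s), 0)
  }
  h <- h / sum(h)
  out <- stats::convolve(drive, rev(h), type = "open")
  out[seq_along(drive)]
}

#' Simulate a transcranial Doppler blood-flow-velocity recording
#'
#' Generates a pulsatile middle-cerebral-artery velocity trace whose
#' beat-averaged envelope follows the convolved drive:
#' `v(t) = baseline * (1 + gain * (h * drive)(t) / 100) * pulse(t) + noise`.
#' The drive is taken from the `ber` column of an RGE series (resampled
#' over breath holds and z-scored by default) or from any two-column
#' `(time_s, value)` table with `drive_scale = "none"`. The cardiac pulse
#' is a half-sine systolic upstroke repeating at `heart_rate_bpm`, with
#' unit mean over each beat so beat averaging recovers the envelope.
#'
#' @param protocol a `protocol_schedule` (defines the record length).
#' @param rge_drive an `rge_series` (uses `ber`) or a tibble with
#'   `time_s`/`value` columns.
#' @param params a [hemo_sim_params()] list.
#' @param fs output sampling rate, Hz.
#' @param baseline_cm_s baseline mean velocity, cm/s.
#' @param heart_rate_bpm cardiac rate, beats/min.
#' @param pulsatility peak-to-mean amplitude of the cardiac waveform
#'   (relative units).
#' @param drive_scale `"zscore"` (default) or `"none"`.
#' @return A `cbfv_trace` tibble with `time_s` and `velocity` (cm/s),
#'   with attributes `fs` and `truth` (the noiseless beat-averaged
#'   percent-change envelope).
#' @export
simulate_cbfv <- function(protocol, rge_drive, params = hemo_sim_params(),
                          fs = 25, baseline_cm_s = 60, heart_rate_bpm = 66,
                          pulsatility = 0.5,
                          drive_scale = c("zscore", "none")) {
  drive_scale <- match.arg(drive_scale)
  if (!inherits(params, "hemo_sim_params")) params <- do.call(hemo_sim_params, params)
  if (is.null(rge_drive) || nrow(rge_drive) == 0) {
    stop_cvreact("Empty drive series.", "cvreact_empty_drive")
  }
  total <- attr(protocol, "total_duration_s")
  time_s <- seq(0, total, by = 1 / fs)

  if ("ber" %in% names(rge_drive)) {
    res <- interpolate_over_breath_holds(rge_drive, grid_dt_s = 1 / fs,
                                         metrics = "ber")
    dr <- approx(res$time_s, res$ber, xout = time_s, rule = 2)$y
  } else {
    dr <- approx(rge_drive$time_s, rge_drive$value, xout = time_s, rule = 2)$y
  }
  if (drive_scale == "zscore") dr <- (dr - mean(dr)) / sd(dr)

  env <- hemo_kernel_convolve(dr, 1 / fs, params$response_delay_s,
                              params$dispersion_tau_s)
  envelope_pct <- params$coupling_gain * env

  beat_period <- 60 / heart_rate_bpm
  phase <- (time_s %% beat_period) / beat_period
  w <- sin(pi * pmin(phase / 0.35, 1))^2       # systolic upstroke + decay
  pulse <- 1 + pulsatility * (w - mean(w))

  noise <- if (params$noise_sd > 0) {
    with_seed(params$seed,
              as.numeric(stats::arima.sim(list(ar = max(params$ar1_coef, 1e-8)),
                                          n = length(time_s),
                                          sd = params$noise_sd *
                                            sqrt(1 - params$ar1_coef^2))))
  } else 0

  velocity <- baseline_cm_s * (1 + envelope_pct / 100) * pulse + noise
  out <- tibble::new_tibble(
    tibble::tibble(time_s = time_s, velocity = velocity),
    class = "cbfv_trace", fs = fs,
    truth = tibble::tibble(time_s = time_s, envelope_pct = envelope_pct))
  out
}

#' Simulate a small 4D BOLD dataset with known ground-truth CVR
#'
#' Each in-mask voxel time series is
#' `100 * (1 + truth_cvr(v) * (h * regressor)(t) / 100) + AR(1) noise`,
#' i.e. a mean-100 signal whose percent change follows the convolved
#' regressor with a voxelwise slope given by the ground-truth CVR map.
#' The parcellation splits the grid into left/right gray and white
#' blocks (labels 1--4) by default.
#'
#' @param protocol a `protocol_schedule` (used for the record length when
#'   `n_volumes` is `NULL`).
#' @param regressor tibble with `time_s` and `value` (the vasoactive
#'   drive in its native units).
#' @param truth_cvr 3D array of true slopes (percent BOLD per unit
#'   regressor), dimensions `grid`.
#' @param params a [hemo_sim_params()] list (`coupling_gain` is unused
#'   here; slopes come from `truth_cvr`).
#' @param grid integer triple `(nx, ny, nz)`.
#' @param tr_s repetition time, seconds.
#' @param n_volumes number of volumes; default covers the protocol.
#' @param mask 3D logical array (default all `TRUE`).
#' @param parcellation 3D integer array of region labels (0 background).
#' @param voxel_dims_mm voxel dimensions, mm.
#' @return A `bold_dataset`: list with `data` (4D array), `tr_s`, `mask`,
#'   `parcellation`, `voxel_dims_mm`, `truth_cvr`, `regressor`, `params`.
#' @export
simulate_bold <- function(protocol, regressor, truth_cvr,
                          params = hemo_sim_params(), grid = c(8, 8, 4),
                          tr_s = 1.45, n_volumes = NULL, mask = NULL,
                          parcellation = NULL,
                          voxel_dims_mm = c(3.4, 3.4, 6)) {
  if (!inherits(params, "hemo_sim_params")) params <- do.call(hemo_sim_params, params)
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3L)
  if (!identical(dim(truth_cvr), grid)) {
    if (length(truth_cvr) == 1L) {
      truth_cvr <- array(truth_cvr, dim = grid)
    } else {
      stop_cvreact("`truth_cvr` dimensions must match `grid`.",
                   "cvreact_grid_mismatch")
    }
  }
  if (is.null(mask)) mask <- array(TRUE, dim = grid)
  if (!identical(dim(mask), grid)) {
    stop_cvreact("`mask` dimensions must match `grid`.",
                 "cvreact_grid_mismatch")
  }
  if (is.null(parcellation)) parcellation <- default_parcellation(grid)

  total <- attr(protocol, "total_duration_s")
  n_vol <- n_volumes %||% floor(total / tr_s)
  t_vol <- (seq_len(n_vol) - 1L) * tr_s
  reg <- approx(regressor$time_s, regressor$value, xout = t_vol, rule = 2)$y
  conv <- hemo_kernel_convolve(reg, tr_s, params$response_delay_s,
                               params$dispersion_tau_s)

  n_vox <- prod(grid)
  slopes <- as.vector(truth_cvr)
  # signal: voxels x time
  sig <- 100 * (1 + outer(slopes, conv) / 100)
  if (params$noise_sd > 0) {
    noise <- with_seed(params$seed, {
      eps <- matrix(rnorm(n_vox * n_vol,
                          sd = params$noise_sd * sqrt(1 - params$ar1_coef^2)),
                    n_vox, n_vol)
      out <- eps
      if (params$ar1_coef != 0) {
        out[, 1] <- eps[, 1] / sqrt(1 - params$ar1_coef^2)
        for (j in 2:n_vol) out[, j] <- params$ar1_coef * out[, j - 1] + eps[, j]
      }
      out
    })
    sig <- sig + noise
  }
  data4d <- array(sig, dim = c(grid, n_vol))
  data4d[array(!mask, dim = c(grid, n_vol))] <- 0

  structure(list(data = data4d, tr_s = tr_s, mask = mask,
                 parcellation = parcellation,
                 voxel_dims_mm = voxel_dims_mm, truth_cvr = truth_cvr,
                 regressor = tibble::tibble(time_s = t_vol, value = reg),
                 params = params),
            class = "bold_dataset")
}

# Four-block parcellation: left/right x dorsal(gray)/ventral(white)
default_parcellation <- function(grid) {
  parc <- array(0L, dim = grid)
  nx <- grid[1]; nz <- grid[3]
  left <- seq_len(floor(nx / 2))
  upper <- seq_len(ceiling(nz / 2))
  parc[left, , upper] <- 1L                      # LGM
  parc[setdiff(seq_len(nx), left), , upper] <- 2L # RGM
  parc[left, , setdiff(seq_len(nz), upper)] <- 3L # LWM
  parc[setdiff(seq_len(nx), left), , setdiff(seq_len(nz), upper)] <- 4L # RWM
  parc
}

#' @export
print.bold_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_dataset: %dx%dx%d voxels, %d volumes, TR %.2f s>\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}
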