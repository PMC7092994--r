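#' Parameters for the gas-trace simulator
#'
#' Collects the physiological and technical parameters of
#' [simulate_gas_traces()]. Defaults describe a healthy adult breathing
#' room air through a nasal sampling line: end-tidal plateaus near
#' 38 mmHg CO2 / 110 mmHg O2, inspired levels near ambient (a small CO2
#' dead-space offset, O2 slightly below the ambient 150 mmHg because of
#' line mixing), and breath periods of about 4.5 s.
#'
#' During a breath hold the analyzer keeps reporting the last expired
#' sample, so the accumulated gas exchange surfaces in the first
#' post-hold breath: its within-breath swings are enlarged by
#' `bh_dpo2_drift` / `bh_dpco2_drift` mmHg per second of apnea (the O2
#' drift is about four times the CO2 drift, matching the relative
#' magnitudes of breath-hold-induced swings). Recovery back to baseline
#' is a slow exponential for O2 (`po2_recovery_tau_s`) and a faster
#' biexponential with a hyperventilation undershoot for CO2
#' (`pco2_recovery_tau_s`, `pco2_undershoot`): the deep recovery breaths
#' blow off CO2 quickly while the O2 debt persists.
#'
#' @param fs sampling rate, Hz.
#' @param baseline_petco2,baseline_peto2 baseline end-tidal partial
#'   pressures, mmHg.
#' @param inspired_pco2,inspired_po2 inspired partial pressures read at end
#'   inspiration, mmHg.
#' @param breath_period_mean,breath_period_sd breath period distribution, s.
#' @param bh_dpo2_drift,bh_dpco2_drift growth of the within-breath O2/CO2
#'   swing per second of apnea, mmHg/s.
#' @param po2_recovery_tau_s,pco2_recovery_tau_s,pco2_undershoot post-hold
#'   recovery time constants (s) and the relative size of the CO2
#'   undershoot lobe.
#' @param et_jitter_sd_pco2,et_jitter_sd_po2 per-breath end-tidal
#'   variability (mmHg); `jitter_corr` is the correlation between the CO2
#'   and O2 components, giving the moderate within-session coupling of
#'   the two swings.
#' @param channel_drift_pco2,channel_drift_po2 per-breath random-walk
#'   step (mmHg) of a slow whole-channel baseline drift -- analyzer
#'   baseline wander plus genuine slow end-tidal drift. It shifts
#'   inspired and expired readings together, so end-tidal levels absorb
#'   it while the within-breath swings (and hence bER) do not.
#' @param recovery_breath_slowing relative prolongation of the first
#'   recovery breaths after a hold (deep slow breaths), decaying with a
#'   15 s time constant.
#' @param hypercapnia_tau_s approach time constant of the end-tidal CO2
#'   step under exogenous CO2 epochs, s.
#' @param noise_sd additive Gaussian sample noise on both channels, mmHg.
#' @param seed integer seed.
#' @return a list of class `gas_sim_params`.
#' @export
gas_sim_params <- function(fs = 50,
                           baseline_petco2 = 38,
                           baseline_peto2 = 110,
                           inspired_pco2 = 2,
                           inspired_po2 = 148,
                           breath_period_mean = 4.5,
                           breath_period_sd = 0.4,
                           bh_dpo2_drift = 1.0,
                           bh_dpco2_drift = 0.25,
                           po2_recovery_tau_s = 12,
                           pco2_recovery_tau_s = 7,
                           pco2_undershoot = 0.8,
                           et_jitter_sd_pco2 = 0.3,
                           et_jitter_sd_po2 = 1.0,
                           jitter_corr = 0.75,
                           channel_drift_pco2 = 0.4,
                           channel_drift_po2 = 0.5,
                           recovery_breath_slowing = 0.5,
                           hypercapnia_tau_s = 10,
                           noise_sd = 0.3,
                           seed = 1L) {
  p <- as.list(environment())
  assert_scalar_number(p$fs, "fs", lower = 0, strict_lower = TRUE)
  assert_scalar_number(p$baseline_petco2, "baseline_petco2", lower = 0,
                       strict_lower = TRUE)
  if (p$baseline_peto2 <= p$baseline_petco2) {
    stop_cvreact("baseline_peto2 must exceed baseline_petco2.",
                 "cvreact_invalid_parameter")
  }
  if (p$inspired_pco2 >= p$baseline_petco2) {
    stop_cvreact("inspired_pco2 must lie below the end-tidal CO2 plateau.",
                 "cvreact_invalid_parameter")
  }
  if (p$inspired_po2 <= p$baseline_peto2) {
    stop_cvreact("inspired_po2 must lie above the end-tidal O2 plateau.",
                 "cvreact_invalid_parameter")
  }
  assert_scalar_number(p$bh_dpo2_drift, "bh_dpo2_drift", lower = 0)
  assert_scalar_number(p$bh_dpco2_drift, "bh_dpco2_drift", lower = 0)
  assert_scalar_number(p$breath_period_mean, "breath_period_mean",
                       lower = 1, strict_lower = TRUE)
  assert_scalar_number(p$noise_sd, "noise_sd", lower = 0)
  structure(p, class = "gas_sim_params")
}

# cubic smoothstep on [0, 1]
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Simulate nasal-sampled PO2/PCO2 traces under a challenge protocol
#'
#' Renders a uniformly sampled capnogram-like pair of gas traces for the
#' given protocol. Each breath is a piecewise-smooth trapezoid: a fast
#' inspiratory transition to the inspired level with the extreme exactly
#' at end inspiration, then a fast expiratory transition followed by a
#' gently sloped plateau reaching the end-tidal value exactly at end
#' expiration, so both markers are well defined. Breaths tile each
#' free-breathing segment exactly (periods drawn from the seeded RNG and
#' rescaled to fit), the trace holds at the last expired value during
#' breath-hold epochs, and the first post-hold breath carries the
#' accumulated exchange (see [gas_sim_params()]). Exogenous CO2 epochs
#' raise the end-tidal CO2 plateau toward the labelled +4 / +8 mmHg step
#' with a first-order approach.
#'
#' @param protocol a [generate_protocol()] schedule.
#' @param params a [gas_sim_params()] list.
#' @return A `gas_traces` tibble with columns `time_s`, `po2`, `pco2`,
#'   `resp`, carrying attributes `fs`, `protocol`, `params` and `truth`
#'   (the ground-truth breath table used to render the trace).
#' @export
simulate_gas_traces <- function(protocol, params = gas_sim_params()) {
  stopifnot(inherits(protocol, "protocol_schedule"))
  if (!inherits(params, "gas_sim_params")) params <- do.call(gas_sim_params, params)
  total <- attr(protocol, "total_duration_s")
  p <- params

  holds <- protocol[protocol$label == "breath_hold", , drop = FALSE]
  hold_int <- cbind(holds$onset_s, holds$onset_s + holds$duration_s)

  # free-breathing segments: complement of the holds within [0, total]
  seg_start <- c(0, hold_int[, 2])
  seg_end <- c(hold_int[, 1], total)
  keep <- seg_end - seg_start > p$breath_period_mean
  seg_start <- seg_start[keep]; seg_end <- seg_end[keep]

  post_hold_starts <- if (nrow(holds) > 0) hold_int[, 2] else numeric(0)
  breaths <- with_seed(p$seed, {
    purrr::map2_dfr(seg_start, seg_end, function(a, b) {
      len <- b - a
      n_b <- max(1L, round(len / p$breath_period_mean))
      dur <- rnorm(n_b, p$breath_period_mean, p$breath_period_sd)
      dur <- pmax(dur, 0.4 * p$breath_period_mean)
      if (a %in% post_hold_starts && p$recovery_breath_slowing > 0) {
        # deep, slow recovery breaths right after the apnea
        t_rel <- c(0, cumsum(dur))[seq_along(dur)]
        dur <- dur * (1 + p$recovery_breath_slowing * exp(-t_rel / 15))
      }
      dur <- dur * len / sum(dur)            # tile the segment exactly
      ends <- a + cumsum(dur)
      tibble::tibble(t_start = c(a, head(ends, -1)), t_end = ends,
                     duration = dur)
    }) -> tab
    n <- nrow(tab)
    z1 <- rnorm(n); z2 <- rnorm(n)
    tab$jit_pco2 <- p$et_jitter_sd_pco2 * z1
    tab$jit_po2 <- p$et_jitter_sd_po2 *
      (p$jitter_corr * z1 + sqrt(1 - p$jitter_corr^2) * z2)
    # whole-channel baseline drift: shifts inspired and expired readings
    # of a breath together, leaving the within-breath swings untouched
    tab$drift_pco2 <- cumsum(rnorm(n, 0, p$channel_drift_pco2))
    tab$drift_po2 <- cumsum(rnorm(n, 0, p$channel_drift_po2))
    tab
  })

  # post-hold excursions, evaluated at each breath start so the first
  # post-hold breath reflects the full accumulated drift
  exc_pco2 <- numeric(nrow(breaths))
  exc_po2 <- numeric(nrow(breaths))
  if (nrow(holds) > 0) {
    for (i in seq_len(nrow(breaths))) {
      prior <- which(hold_int[, 2] <= breaths$t_start[i] + 1e-9)
      if (length(prior) > 0) {
        h <- max(prior)
        dt_h <- breaths$t_start[i] - hold_int[h, 2]
        dur_h <- hold_int[h, 2] - hold_int[h, 1]
        a_c <- p$bh_dpco2_drift * dur_h
        a_o <- p$bh_dpo2_drift * dur_h
        u <- p$pco2_undershoot
        exc_pco2[i] <- a_c * ((1 + u) * exp(-dt_h / p$pco2_recovery_tau_s) -
                                u * exp(-dt_h / (2.5 * p$pco2_recovery_tau_s)))
        exc_po2[i] <- a_o * exp(-dt_h / p$po2_recovery_tau_s)
      }
    }
  }

  # end-tidal CO2 target under exogenous CO2 epochs (first-order approach)
  et_base <- rep(p$baseline_petco2, nrow(breaths))
  if (attr(protocol, "kind") == "co2") {
    step_of <- function(t) {
      row <- which(protocol$onset_s <= t & t < protocol$onset_s + protocol$duration_s)
      if (length(row) == 0) return(0)
      switch(protocol$label[row[1]], hypercapnia_4 = 4, hypercapnia_8 = 8, 0)
    }
    state <- 0
    for (i in seq_len(nrow(breaths))) {
      target <- step_of(breaths$t_start[i])
      state <- state + (target - state) *
        (1 - exp(-breaths$duration[i] / p$hypercapnia_tau_s))
      et_base[i] <- p$baseline_petco2 + state
    }
  }

  breaths$et_pco2 <- et_base + exc_pco2 + breaths$jit_pco2 + breaths$drift_pco2
  breaths$ex_po2 <- p$baseline_peto2 - exc_po2 - breaths$jit_po2 +
    breaths$drift_po2
  breaths$insp_pco2 <- p$inspired_pco2 + breaths$drift_pco2
  breaths$insp_po2 <- p$inspired_po2 + breaths$drift_po2
  breaths$t_end_insp <- breaths$t_start + 0.4 * breaths$duration

  # render the sampled trace
  n_samp <- floor(total * p$fs) + 1L
  time_s <- (seq_len(n_samp) - 1L) / p$fs
  pco2 <- rep(NA_real_, n_samp)
  po2 <- rep(NA_real_, n_samp)
  resp <- numeric(n_samp)

  trough_c <- 0.5; plateau_c <- 1.0      # mmHg slopes of the CO2 trapezoid
  trough_o <- 1.0; plateau_o <- 2.0      # larger margins for the O2 swing

  prev_et <- p$baseline_petco2
  prev_ex <- p$baseline_peto2
  for (i in seq_len(nrow(breaths))) {
    b <- breaths[i, ]
    idx <- which(time_s >= b$t_start - 1e-9 & time_s < b$t_end - 1e-9)
    if (length(idx) == 0) { prev_et <- b$et_pco2; prev_ex <- b$ex_po2; next }
    tt <- time_s[idx] - b$t_start
    ti <- 0.4 * b$duration; te <- b$duration - ti
    insp <- tt < ti
    u <- tt[insp] / ti
    v <- (tt[!insp] - ti) / te

    ramp_u <- smoothstep(u / 0.35)
    lin_u <- pmax((u - 0.35) / 0.65, 0)
    ramp_v <- smoothstep(v / 0.35)
    lin_v <- pmax((v - 0.35) / 0.65, 0)

    c_insp <- prev_et + (b$insp_pco2 + trough_c - prev_et) * ramp_u -
      trough_c * lin_u
    c_exp <- b$insp_pco2 + (b$et_pco2 - plateau_c - b$insp_pco2) * ramp_v +
      plateau_c * lin_v
    o_insp <- prev_ex + (b$insp_po2 - trough_o - prev_ex) * ramp_u +
      trough_o * lin_u
    o_exp <- b$insp_po2 + (b$ex_po2 + plateau_o - b$insp_po2) * ramp_v -
      plateau_o * lin_v

    pco2[idx] <- c(c_insp, c_exp)
    po2[idx] <- c(o_insp, o_exp)
    resp[idx] <- c(sin(pi * u), -sin(pi * v))
    prev_et <- b$et_pco2
    prev_ex <- b$ex_po2
  }

  # holds: the analyzer keeps reporting the last expired sample, so fill
  # each hold with the pre-hold breath's exact end-tidal values
  for (h in seq_len(nrow(holds))) {
    pre <- which(breaths$t_end <= hold_int[h, 1] + 1e-9)
    idx <- which(time_s >= hold_int[h, 1] - 1e-9 & time_s < hold_int[h, 2] - 1e-9)
    if (length(pre) > 0 && length(idx) > 0) {
      pco2[idx] <- breaths$et_pco2[max(pre)]
      po2[idx] <- breaths$ex_po2[max(pre)]
      resp[idx] <- 0
    }
  }
  # any unfilled samples (record tail): carry the last value forward
  filled <- !is.na(pco2)
  if (!filled[1]) {
    pco2[1] <- p$baseline_petco2; po2[1] <- p$baseline_peto2; filled[1] <- TRUE
  }
  carry <- cummax(ifelse(filled, seq_len(n_samp), 0L))
  pco2 <- pco2[carry]
  po2 <- po2[carry]

  if (p$noise_sd > 0) {
    noise <- with_seed(child_seed(p$seed, 1L),
                       rnorm(2L * n_samp, 0, p$noise_sd))
    pco2 <- pco2 + noise[seq_len(n_samp)]
    po2 <- po2 + noise[n_samp + seq_len(n_samp)]
  }

  truth <- tibble::tibble(
    t_end_insp_s = breaths$t_end_insp,
    t_end_exp_s = breaths$t_end,
    inspired_pco2 = breaths$insp_pco2,
    expired_pco2 = breaths$et_pco2,
    inspired_po2 = breaths$insp_po2,
    expired_po2 = breaths$ex_po2
  )

  new_gas_traces(tibble::tibble(time_s = time_s, po2 = po2, pco2 = pco2,
                                resp = resp),
                 fs = p$fs, protocol = protocol, params = p, truth = truth)
}

new_gas_traces <- function(tbl, fs, protocol = NULL, params = NULL,
                           truth = NULL) {
  tibble::new_tibble(tbl, class = "gas_traces", fs = fs, protocol = protocol,
                     params = params, truth = truth)
}

#' @export
print.gas_traces <- function(x, ...) {
  cat(sprintf("<gas_traces: %d samples @ %g Hz, %.0f s>\n",
              nrow(x), attr(x, "fs"), max(x$time_s)))
  NextMethod()
}
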