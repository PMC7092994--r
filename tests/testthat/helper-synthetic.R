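# Shared synthetic fixtures. Expensive objects are memoized so several
# test files can reuse one simulation.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

std_protocol <- function(seed = 1L) {
  generate_protocol("breath_hold", n_epochs = 6, bh_duration_s = 30,
                    free_range_s = c(60, 90), seed = seed)
}

# deterministic trace: no sample noise, no breath-to-breath variability
noiseless_params <- function(...) {
  gas_sim_params(noise_sd = 0, et_jitter_sd_pco2 = 0, et_jitter_sd_po2 = 0,
                 breath_period_sd = 0, channel_drift_pco2 = 0,
                 channel_drift_po2 = 0, ...)
}

noiseless_gas <- function() {
  fixture("noiseless_gas", simulate_gas_traces(std_protocol(), noiseless_params()))
}

default_gas <- function() {
  fixture("default_gas", simulate_gas_traces(std_protocol(), gas_sim_params()))
}

default_rge <- function() {
  fixture("default_rge", {
    g <- default_gas()
    suppressMessages(compute_rge_metrics(detect_breath_markers(g, resp = g$resp)))
  })
}

# minimal hand-built wavelet-coherence object for TAC oracle tests
fake_wtc <- function(coherence, phase, periods, times, coi, threshold) {
  structure(list(times = times, scales = periods / (4 * pi / (6 + sqrt(38))),
                 periods = periods, freqs = 1 / periods,
                 coherence = coherence, phase = phase, coi = coi,
                 sig_threshold = threshold,
                 params = list(dt = diff(times[1:2]), scales_per_octave = 12,
                               period_range_s = range(periods))),
            class = "wtc_result")
}
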