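# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

quiet_cfg <- function(seed = 1L, fs = 5000, dur = 4, noise = 0, ...) {
  sim_config(seed = seed, sampling_rate = fs, duration = dur,
             noise_sd = noise, ...)
}

# One endocytic pore trace with known Cv and duration.
pore_trace <- function(D, Cv = 1e-15, noise = 0, seed = 1L, fs = 5000,
                       t0 = 2, dur = 4, ...) {
  cfg <- quiet_cfg(seed = seed, fs = fs, dur = dur, noise = noise, ...)
  simulate_fission_trace(list(pore_event(t0, "endocytic", Cv,
                                         pore_duration = D)), cfg)
}

# Plain trapezoidal integration, written out independently of the package.
trapz_q <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Noise SD (pre-filter) that yields a given post-filter SNR for a step of
# `step_f` farads.
noise_for_snr <- function(step_f, snr, cfg) {
  omega <- 2 * pi * cfg$lockin_frequency
  (step_f * omega / snr) / lockin_noise_gain(cfg)
}
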