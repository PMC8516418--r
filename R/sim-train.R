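#' Simulate a depressing amplitude train
#'
#' Geometric relaxation toward a steady state: the n-th normalized amplitude
#' is `a_n = a_ss + (1 - a_ss) * r^(n-1)`, so the first response is 1 and the
#' sequence decreases monotonically toward `a_ss` (noiseless case).
#'
#' @param n_stim number of stimuli.
#' @param a_ss steady-state normalized amplitude in `[0, 1]`.
#' @param r geometric rate in `[0, 1)`.
#' @param noise_sd additive Gaussian noise SD on each amplitude.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return numeric vector of `n_stim` amplitudes.
#' @export
simulate_depressing_train <- function(n_stim, a_ss, r, noise_sd = 0,
                                      seed = 1L) {
  stopifnot(n_stim >= 1, a_ss >= 0, a_ss <= 1, r >= 0)
  if (r >= 1) stop("geometric rate r must be < 1")
  a <- a_ss + (1 - a_ss) * r^(seq_len(n_stim) - 1)
  if (noise_sd > 0)
    a <- a + with_seed(seed, stats::rnorm(n_stim, 0, noise_sd))
  a
}

#' Train recording container
#'
#' @param time seconds. @param response response trace (pA for IPSCs,
#'   normalized fluorescence for iGluSnFR), positive-going.
#' @param stim_times stimulus times, s, strictly increasing.
#' @param modality `"ipsc"` or `"iglusnfr"`.
#' @param sampling_rate samples/s.
#' @export
train_recording <- function(time, response, stim_times,
                            modality = c("ipsc", "iglusnfr"),
                            sampling_rate) {
  modality <- match.arg(modality)
  stopifnot(length(time) == length(response), all(diff(stim_times) > 0))
  structure(list(time = time, response = response, stim_times = stim_times,
                 modality = modality, sampling_rate = sampling_rate),
            class = "train_recording")
}

#' Simulate a summating evoked-response train
#'
#' Each stimulus contributes a response of known unitary amplitude with a
#' linear rise (`rise_time`) and exponential decay (`tau_decay`); successive
#' responses summate, so raw peaks ride on the residual of earlier responses.
#' This is the forward model inverted by [extract_train_amplitudes()].
#'
#' @param amplitudes unitary (true) amplitudes per stimulus.
#' @param frequency stimulation frequency, Hz.
#' @param tau_decay response decay time constant, s.
#' @param rise_time linear rise duration, s.
#' @param cfg a [sim_config()] (`noise_sd` in trace units).
#' @param onset time of first stimulus, s.
#' @param modality passed to [train_recording()].
#' @return list with `rec` (a `train_recording`) and `truth`.
#' @export
simulate_summating_train <- function(amplitudes, frequency, tau_decay,
                                     rise_time = 0.002, cfg, onset = 0.1,
                                     modality = "ipsc") {
  stopifnot(inherits(cfg, "sim_config"), all(amplitudes >= 0),
            tau_decay > 0, rise_time >= 0)
  n_stim <- length(amplitudes)
  stim_times <- onset + (seq_len(n_stim) - 1) / frequency
  if (max(stim_times) + rise_time >= cfg$duration)
    stop("train must end before the trace does")
  n <- round(cfg$sampling_rate * cfg$duration)
  tt <- (seq_len(n) - 1L) / cfg$sampling_rate
  y <- numeric(n)
  for (i in seq_len(n_stim)) {
    t0 <- stim_times[i]
    tp <- t0 + rise_time
    if (rise_time > 0) {
      idx <- tt >= t0 & tt < tp
      y[idx] <- y[idx] + amplitudes[i] * (tt[idx] - t0) / rise_time
    }
    idx <- tt >= tp
    y[idx] <- y[idx] + amplitudes[i] * exp(-(tt[idx] - tp) / tau_decay)
  }
  if (cfg$noise_sd > 0)
    y <- y + with_seed(cfg$seed, stats::rnorm(n, 0, cfg$noise_sd))
  rec <- train_recording(time = tt, response = y, stim_times = stim_times,
                         modality = modality,
                         sampling_rate = cfg$sampling_rate)
  truth <- structure(list(kind = "train", amplitudes = amplitudes,
                          tau_decay = tau_decay, rise_time = rise_time,
                          stim_times = stim_times),
                     class = "ground_truth")
  list(rec = rec, truth = truth)
}
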