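#' Amperometric trace container
#'
#' @param time seconds. @param I oxidation current, pA.
#' @param sampling_rate samples/s. @param stim_time stimulation time, s.
#' @export
amperometric_trace <- function(time, I, sampling_rate, stim_time = 0) {
  stopifnot(length(time) == length(I), all(is.finite(I)))
  structure(list(time = time, I = I, sampling_rate = sampling_rate,
                 stim_time = stim_time),
            class = "amperometric_trace")
}

#' Simulate a carbon-fiber amperometric recording
#'
#' Each spike is rendered as an optional pre-spike foot (a plateau of
#' `foot_amp` pA lasting `foot_duration` s), a raised-cosine rise of duration
#' `rise_time` from the foot level to `peak`, and an exponential decay with
#' time constant `tau_decay` back to baseline. A footless, instant-rise spike
#' has total charge `peak * tau_decay` (in pA*s = pC).
#'
#' @param spikes data.frame with columns `t` (rise-onset time, s), `peak`
#'   (pA), `tau_decay` (s), and optionally `rise_time` (s, default 0),
#'   `foot_amp` (pA, default 0), `foot_duration` (s, default 0). Rows must be
#'   sorted by `t`.
#' @param cfg a [sim_config()]; `noise_sd` in pA.
#' @param stim_time stimulation time recorded in the trace metadata, s.
#' @return list with `trace` (an `amperometric_trace`) and `truth`.
#' @export
simulate_amperometric_trace <- function(spikes, cfg, stim_time = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(spikes) || nrow(as.data.frame(spikes)) == 0)
    spikes <- data.frame(t = numeric(0), peak = numeric(0),
                         tau_decay = numeric(0))
  spikes <- as.data.frame(spikes)
  for (col in c("rise_time", "foot_amp", "foot_duration"))
    if (is.null(spikes[[col]])) spikes[[col]] <- rep(0, nrow(spikes))
  if (nrow(spikes) > 0) {
    stopifnot(all(spikes$peak > 0), all(spikes$tau_decay > 0),
              all(spikes$rise_time >= 0), all(spikes$foot_amp >= 0),
              all(spikes$foot_duration >= 0),
              !is.unsorted(spikes$t))
  }
  n <- round(cfg$sampling_rate * cfg$duration)
  tt <- (seq_len(n) - 1L) / cfg$sampling_rate
  I <- numeric(n)
  for (k in seq_len(nrow(spikes))) {
    s <- spikes[k, ]
    t_peak <- s$t + s$rise_time
    if (s$foot_duration > 0 && s$foot_amp > 0) {
      idx <- tt >= (s$t - s$foot_duration) & tt < s$t
      I[idx] <- I[idx] + s$foot_amp
    }
    if (s$rise_time > 0) {
      idx <- tt >= s$t & tt < t_peak
      ph <- (tt[idx] - s$t) / s$rise_time
      I[idx] <- I[idx] + s$foot_amp +
        (s$peak - s$foot_amp) * (1 - cos(pi * ph)) / 2
    }
    idx <- tt >= t_peak
    I[idx] <- I[idx] + s$peak * exp(-(tt[idx] - t_peak) / s$tau_decay)
  }
  if (cfg$noise_sd > 0)
    I <- I + with_seed(cfg$seed, stats::rnorm(n, 0, cfg$noise_sd))
  trace <- amperometric_trace(time = tt, I = I,
                              sampling_rate = cfg$sampling_rate,
                              stim_time = stim_time)
  truth <- structure(list(kind = "amperometry",
                          spikes = spikes, stim_time = stim_time),
                     class = "ground_truth")
  list(trace = trace, truth = truth)
}
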