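#' Patch-current trace container
#'
#' Ionic current recorded through the cell-attached pipette during a
#' double-patch experiment, with the voltage held across the patch membrane.
#'
#' @param time seconds. @param I current in pA (as-plotted pipette current).
#' @param V_patch voltage across the patch membrane, mV.
#' @param sampling_rate samples/s. @param filter_hz low-pass corner, Hz.
#' @param t_event time of the linked capacitance event, seconds (or NA).
#' @export
patch_current_trace <- function(time, I, V_patch, sampling_rate,
                                filter_hz = 500, t_event = NA_real_) {
  stopifnot(length(time) == length(I), all(diff(time) > 0))
  structure(list(time = time, I = I, V_patch = V_patch,
                 sampling_rate = sampling_rate, filter_hz = filter_hz,
                 t_event = t_event),
            class = "patch_current_trace")
}

#' Simulate a patch current with an endocytosis-associated drift
#'
#' Forward model for the current-drift analysis. The recorded (as-plotted)
#' patch current is a linear baseline plus, at `t_event`, a step of
#' `+g_loss_model(V) * V`: internalisation of a vesicle carrying open
#' channels removes their current from the patch, and in the plotting
#' convention used here a loss of outward membrane current at positive
#' voltage appears as an upward drift of the recorded current (and a loss of
#' inward current at negative voltage as a downward drift).
#'
#' The step is low-pass filtered with a single-pole filter at `filter_hz`
#' (default 500 Hz) and white Gaussian noise of SD `cfg$noise_sd` (pA) is
#' added.
#'
#' @param V patch membrane voltage, volts.
#' @param g_loss_model function of voltage (volts) returning the conductance
#'   lost at the event, siemens.
#' @param t_event event time, seconds (must lie inside the trace).
#' @param baseline_slope baseline drift, pA per second.
#' @param cfg a [sim_config()]; `lockin_*` fields are ignored here.
#' @param baseline_offset baseline current at t = 0, pA.
#' @param filter_hz low-pass corner frequency, Hz.
#' @return list with `trace` (a `patch_current_trace`, current in pA,
#'   `V_patch` in mV) and `truth` (injected step size `delta_I_pA` etc.).
#' @export
simulate_patch_current <- function(V, g_loss_model, t_event, baseline_slope,
                                   cfg, baseline_offset = 0,
                                   filter_hz = 500) {
  stopifnot(inherits(cfg, "sim_config"),
            t_event > 0, t_event < cfg$duration)
  g <- g_loss_model(V)
  if (!is.finite(g) || g < 0)
    stop("g_loss_model undefined or negative at V = ", V)
  n <- round(cfg$sampling_rate * cfg$duration)
  tt <- (seq_len(n) - 1L) / cfg$sampling_rate
  delta_I <- g * V * 1e12          # amps -> pA
  step <- ifelse(tt >= t_event, delta_I, 0)
  # single-pole low-pass on the step (amplifier filter)
  a <- exp(-2 * pi * filter_hz / cfg$sampling_rate)
  step <- as.numeric(stats::filter((1 - a) * step, a,
                                   method = "recursive", init = step[1]))
  I <- baseline_offset + baseline_slope * tt + step
  if (cfg$noise_sd > 0)
    I <- I + with_seed(cfg$seed, stats::rnorm(n, 0, cfg$noise_sd))
  trace <- patch_current_trace(time = tt, I = I, V_patch = V * 1e3,
                               sampling_rate = cfg$sampling_rate,
                               filter_hz = filter_hz, t_event = t_event)
  truth <- structure(list(kind = "patch_drift", V = V, g_loss = g,
                          delta_I_pA = delta_I, t_event = t_event,
                          baseline_slope = baseline_slope),
                     class = "ground_truth")
  list(trace = trace, truth = truth)
}
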