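#' Simulation configuration
#'
#' Bundles the acquisition parameters shared by all trace generators: sampling
#' rate, duration, additive noise level, and the lock-in amplifier model
#' (carrier frequency plus a cascaded single-pole low-pass output filter).
#'
#' The lock-in output filter is modelled as `lockin_filter_order` identical
#' single-pole stages, each with time constant `lockin_filter_tau`. The
#' defaults (1 ms, 4 poles) correspond to the common hardware setting of a
#' 1 ms filter at 24 dB/octave.
#'
#' @param seed integer RNG seed used for the additive noise.
#' @param sampling_rate samples per second.
#' @param duration trace length in seconds.
#' @param noise_sd standard deviation of additive white Gaussian noise, in the
#'   channel's own units (siemens for admittance, pA for current, a.u. for
#'   fluorescence), applied before the output filter.
#' @param lockin_frequency carrier frequency in Hz; the angular frequency
#'   `omega = 2*pi*lockin_frequency` converts between capacitance and the
#'   imaginary admittance channel.
#' @param lockin_filter_tau output filter time constant in seconds.
#' @param lockin_filter_order number of cascaded single-pole stages.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       sampling_rate = 5000,
                       duration = 10,
                       noise_sd = 0,
                       lockin_frequency = 20000,
                       lockin_filter_tau = 1e-3,
                       lockin_filter_order = 4L) {
  stopifnot(sampling_rate > 0, duration > 0, noise_sd >= 0,
            lockin_frequency > 0, lockin_filter_tau >= 0,
            lockin_filter_order >= 0)
  structure(list(seed = as.integer(seed),
                 sampling_rate = sampling_rate,
                 duration = duration,
                 noise_sd = noise_sd,
                 lockin_frequency = lockin_frequency,
                 lockin_filter_tau = lockin_filter_tau,
                 lockin_filter_order = as.integer(lockin_filter_order)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$duration, "s at", x$sampling_rate, "Hz,",
      "noise_sd =", x$noise_sd, "\n")
  cat("  lock-in:", x$lockin_frequency, "Hz carrier,",
      x$lockin_filter_order, "x single-pole filter, tau =",
      x$lockin_filter_tau * 1e3, "ms\n")
  invisible(x)
}

#' Apply the lock-in output low-pass filter
#'
#' Cascade of identical discrete single-pole stages,
#' `y[n] = a*y[n-1] + (1-a)*x[n]` with `a = exp(-dt/tau)`, initialised at the
#' first sample so a constant input passes unchanged (no startup transient).
#'
#' @param x numeric signal.
#' @param cfg a [sim_config()].
#' @return filtered signal, same length as `x`.
#' @export
lockin_filter <- function(x, cfg) {
  if (cfg$lockin_filter_order == 0L || cfg$lockin_filter_tau <= 0) return(x)
  a <- exp(-1 / (cfg$sampling_rate * cfg$lockin_filter_tau))
  for (i in seq_len(cfg$lockin_filter_order)) {
    x <- as.numeric(stats::filter((1 - a) * x, a, method = "recursive",
                                  init = x[1]))
  }
  x
}

#' White-noise standard-deviation gain of the lock-in filter
#'
#' Ratio of output to input noise SD for white Gaussian input, computed from
#' the filter's impulse response. Useful for choosing a pre-filter `noise_sd`
#' that yields a desired post-filter noise level (and hence a desired SNR).
#'
#' @param cfg a [sim_config()].
#' @param n_impulse length of the impulse response evaluated.
#' @return scalar gain in (0, 1].
#' @export
lockin_noise_gain <- function(cfg, n_impulse = 4096L) {
  imp <- c(1, numeric(n_impulse - 1L))
  h <- lockin_filter(imp, cfg)
  # drop the init-based startup contribution of the first sample
  sqrt(sum(h^2))
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
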