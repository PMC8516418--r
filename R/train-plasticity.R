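#' Extract per-stimulus amplitudes with residual subtraction
#'
#' For each stimulus the raw peak is searched in a window after the stimulus
#' (1-50 ms for IPSCs; the full inter-stimulus interval for frame-rate
#' iGluSnFR data). The residual decay of the preceding responses is fit with
#' a single exponential on the final 30% of the preceding inter-stimulus
#' interval and extrapolated under the current response; the reported
#' amplitude is raw peak minus extrapolated residual at the peak time.
#' Because summated responses with a common decay constant sum to a single
#' exponential, the extraction is exact in the noiseless limit. Amplitudes
#' below 3 x the noise SD are recorded as 0 (failures).
#'
#' @param rec a [train_recording()].
#' @param peak_window `c(min, max)` seconds after each stimulus searched for
#'   the peak; default depends on modality.
#' @param residual_frac fraction of the inter-stimulus interval (its tail)
#'   used for the residual fit.
#' @param noise_sd noise SD for the failure floor; estimated from the
#'   pre-train baseline when NULL.
#' @return numeric vector of residual-subtracted amplitudes, one per
#'   stimulus.
#' @export
extract_train_amplitudes <- function(rec, peak_window = NULL,
                                     residual_frac = 0.3,
                                     noise_sd = NULL) {
  stopifnot(inherits(rec, "train_recording"))
  stim <- rec$stim_times
  isi <- if (length(stim) > 1) min(diff(stim)) else
    max(rec$time) - stim[1]
  if (is.null(peak_window))
    peak_window <- if (rec$modality == "ipsc") c(0.001, 0.050) else
      c(0, isi)
  peak_window[2] <- min(peak_window[2], isi)
  tt <- rec$time
  y <- rec$response
  if (is.null(noise_sd)) {
    pre <- tt < stim[1]
    noise_sd <- if (sum(pre) >= 10) stats::sd(y[pre]) else 0
  }
  n_stim <- length(stim)
  amps <- numeric(n_stim)
  for (i in seq_len(n_stim)) {
    win <- tt >= stim[i] + peak_window[1] & tt <= stim[i] + peak_window[2]
    if (!any(win)) stop("peak window contains no samples; sampling too slow")
    ipk <- which(win)[which.max(y[win])]
    raw <- y[ipk]
    resid <- 0
    if (i > 1) {
      tail_sel <- tt >= stim[i] - residual_frac * (stim[i] - stim[i - 1]) &
        tt < stim[i]
      yt <- y[tail_sel]
      ts <- tt[tail_sel]
      floor_lvl <- max(3 * noise_sd, 1e-12 * max(abs(y)))
      if (sum(tail_sel) >= 3 && all(yt > 0) && max(yt) > floor_lvl) {
        fit <- stats::lm(ly ~ t, data = data.frame(t = ts, ly = log(yt)))
        cf <- stats::coef(fit)
        if (is.finite(cf[2]) && cf[2] < 0)
          resid <- exp(unname(cf[1] + cf[2] * tt[ipk]))
      }
    }
    a <- raw - resid
    amps[i] <- if (a < 3 * noise_sd) 0 else a
  }
  amps
}

#' Normalize a train of amplitudes to its first response
#'
#' @param amplitudes per-stimulus amplitudes.
#' @return `amplitudes / amplitudes[1]`; errors if the first amplitude is
#'   not positive.
#' @export
normalize_train <- function(amplitudes) {
  if (length(amplitudes) < 1 || amplitudes[1] <= 0)
    stop("first amplitude must be positive for normalization")
  amplitudes / amplitudes[1]
}

#' Steady-state depression level
#'
#' Arithmetic mean of the final `last_n` normalized responses. Conventions:
#' `last_n = 10` for 250-pulse IPSC trains, `last_n = 5` for 50-pulse
#' iGluSnFR trains.
#'
#' @param normalized normalized amplitude train.
#' @param last_n number of final responses averaged.
#' @return steady-state value.
#' @export
steady_state <- function(normalized, last_n = 10) {
  if (length(normalized) < last_n)
    stop("train shorter than last_n responses")
  mean(utils::tail(normalized, last_n))
}

#' Paired-pulse ratio
#'
#' @param amplitudes per-stimulus amplitudes (at least 2).
#' @return `amplitudes[2] / amplitudes[1]`.
#' @export
paired_pulse_ratio <- function(amplitudes) {
  if (length(amplitudes) < 2) stop("need at least two amplitudes")
  if (amplitudes[1] <= 0) stop("first amplitude must be positive")
  amplitudes[2] / amplitudes[1]
}
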