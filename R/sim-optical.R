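#' Stimulus protocol
#'
#' @param n_stimuli number of field/electrical stimuli.
#' @param frequency stimulation frequency, Hz.
#' @param onset time of the first stimulus, s.
#' @param acid_windows optional list of `c(start, end)` pairs (seconds) during
#'   which the bath is switched to the pH 5.5 quenching buffer.
#' @export
stim_protocol <- function(n_stimuli, frequency, onset,
                          acid_windows = NULL) {
  stopifnot(n_stimuli >= 1, frequency > 0, onset >= 0)
  if (!is.null(acid_windows)) {
    aw <- do.call(rbind, lapply(acid_windows, function(w) w))
    o <- order(aw[, 1])
    aw <- aw[o, , drop = FALSE]
    if (nrow(aw) > 1 && any(aw[-nrow(aw), 2] > aw[-1, 1]))
      stop("acid windows must not overlap")
    acid_windows <- lapply(seq_len(nrow(aw)), function(i) aw[i, ])
  }
  structure(list(n_stimuli = n_stimuli, frequency = frequency,
                 onset = onset, acid_windows = acid_windows,
                 end = onset + n_stimuli / frequency),
            class = "stim_protocol")
}

#' ROI fluorescence time series container
#'
#' @param time frame times, s. @param F mean ROI fluorescence, a.u.
#' @param stim a [stim_protocol()] or NULL.
#' @param F0 pre-stimulus baseline mean (computed from pre-stimulus frames if
#'   NULL and a protocol is given).
#' @param normalization one of `"none"`, `"dF_over_dFmax"`, `"dF_over_F0"`.
#' @export
roi_timeseries <- function(time, F, stim = NULL, F0 = NULL,
                           normalization = "none") {
  stopifnot(length(time) == length(F), !is.unsorted(time))
  if (is.null(F0) && !is.null(stim)) {
    pre <- time < stim$onset
    F0 <- if (any(pre)) mean(F[pre]) else NA_real_
  }
  structure(list(time = time, F = F, F0 = F0, stim = stim,
                 normalization = normalization),
            class = "roi_timeseries")
}

#' Simulate a pHluorin ROI time series
#'
#' Fluorescence rises linearly during the stimulus train (exocytosis exposing
#' the reporter to neutral pH) and decays mono-exponentially with the
#' endocytic time constant `tau_endo` afterwards, back toward baseline (use
#' `tau_endo = Inf` for a non-retrieving plateau, and `plateau_frac` for
#' incomplete retrieval). With an acid-pulse schedule, surface reporter is
#' quenched during each acid window; the remaining signal above the quenched
#' floor is the trapped component -- vesicles endocytosed but not yet
#' reacidified -- which decays with `tau_reacid`.
#'
#' @param tau_endo endocytic time constant, s (> 0 or Inf).
#' @param stim a [stim_protocol()].
#' @param reacid optional list(`tau_reacid` = s); acid windows are taken from
#'   `stim$acid_windows`.
#' @param cfg a [sim_config()] (`sampling_rate` is the frame rate, Hz;
#'   `noise_sd` in a.u.).
#' @param f0 baseline fluorescence, a.u. @param dF_max peak stimulus-evoked
#'   fluorescence increase, a.u.
#' @param plateau_frac fraction of `dF_max` never retrieved (default 0).
#' @return list with `series` (a `roi_timeseries`) and `truth`.
#' @export
simulate_phluorin_series <- function(tau_endo, stim, reacid = NULL, cfg,
                                     f0 = 100, dF_max = 100,
                                     plateau_frac = 0) {
  stopifnot(inherits(stim, "stim_protocol"), inherits(cfg, "sim_config"),
            tau_endo > 0, plateau_frac >= 0, plateau_frac < 1)
  if (stim$end >= cfg$duration) stop("stimulus must end before the trace does")
  n <- round(cfg$sampling_rate * cfg$duration)
  tt <- (seq_len(n) - 1L) / cfg$sampling_rate
  dF <- numeric(n)
  rising <- tt >= stim$onset & tt < stim$end
  dF[rising] <- dF_max * (tt[rising] - stim$onset) / (stim$end - stim$onset)
  post <- tt >= stim$end
  decaying <- (1 - plateau_frac) * dF_max
  dF[post] <- plateau_frac * dF_max +
    if (is.infinite(tau_endo)) decaying else
      decaying * exp(-(tt[post] - stim$end) / tau_endo)
  F <- f0 + dF
  if (!is.null(stim$acid_windows)) {
    tau_re <- if (!is.null(reacid)) reacid$tau_reacid else 4
    stopifnot(tau_re > 0)
    # endocytosed-but-unreacidified pool at time t (only defined post-stim)
    for (w in stim$acid_windows) {
      idx <- tt >= w[1] & tt < w[2]
      trapped0 <- if (w[1] <= stim$end) 0 else
        decaying * (1 - exp(-(w[1] - stim$end) / tau_endo))
      F[idx] <- trapped0 * exp(-(tt[idx] - w[1]) / tau_re)
    }
  }
  if (cfg$noise_sd > 0)
    F <- F + with_seed(cfg$seed, stats::rnorm(n, 0, cfg$noise_sd))
  series <- roi_timeseries(time = tt, F = F, stim = stim, F0 = f0)
  truth <- structure(list(kind = "phluorin", tau_endo = tau_endo,
                          tau_reacid = if (!is.null(reacid)) reacid$tau_reacid
                                       else NA_real_,
                          f0 = f0, dF_max = dF_max,
                          plateau_frac = plateau_frac),
                     class = "ground_truth")
  list(series = series, truth = truth)
}

#' Simulate a calcium-indicator (GCaMP-style) ROI time series
#'
#' dF/F0-style transient: linear rise during the stimulus window, then
#' exponential decay with `tau_decay` to baseline.
#'
#' @param peak_dff peak amplitude as dF/F0.
#' @param tau_decay decay time constant, s.
#' @param stim a [stim_protocol()]. @param cfg a [sim_config()].
#' @param f0 baseline fluorescence, a.u.
#' @return list with `series` (raw fluorescence) and `truth`.
#' @export
simulate_ca_series <- function(peak_dff, tau_decay, stim, cfg, f0 = 100) {
  stopifnot(tau_decay > 0, peak_dff >= 0)
  n <- round(cfg$sampling_rate * cfg$duration)
  tt <- (seq_len(n) - 1L) / cfg$sampling_rate
  dff <- numeric(n)
  rising <- tt >= stim$onset & tt < stim$end
  dff[rising] <- peak_dff * (tt[rising] - stim$onset) / (stim$end - stim$onset)
  post <- tt >= stim$end
  dff[post] <- peak_dff * exp(-(tt[post] - stim$end) / tau_decay)
  F <- f0 * (1 + dff)
  if (cfg$noise_sd > 0)
    F <- F + with_seed(cfg$seed, stats::rnorm(n, 0, cfg$noise_sd))
  series <- roi_timeseries(time = tt, F = F, stim = stim, F0 = f0)
  truth <- structure(list(kind = "ca", peak_dff = peak_dff,
                          tau_decay = tau_decay, f0 = f0),
                     class = "ground_truth")
  list(series = series, truth = truth)
}

#' Simulate a fluorescence image stack with responding boutons
#'
#' Frames contain Gaussian-profile boutons whose amplitudes follow a shared
#' `timecourse`, on a constant background with additive Gaussian noise.
#'
#' @param dims `c(rows, cols)` frame size in pixels.
#' @param frame_times frame times, s.
#' @param boutons data.frame with columns `row`, `col`, `amp` (peak intensity
#'   above background) and optionally `sigma` (px, default 1.5).
#' @param timecourse numeric vector, one multiplier per frame, scaling every
#'   bouton's amplitude.
#' @param background constant background intensity.
#' @param noise_sd pixel noise SD. @param seed RNG seed.
#' @return an `image_stack`: list(frames = rows x cols x n array,
#'   frame_times).
#' @export
simulate_image_stack <- function(dims, frame_times, boutons, timecourse,
                                 background = 50, noise_sd = 0, seed = 1L) {
  stopifnot(length(timecourse) == length(frame_times))
  boutons <- as.data.frame(boutons)
  if (is.null(boutons$sigma) && nrow(boutons) > 0) boutons$sigma <- 1.5
  base <- matrix(0, dims[1], dims[2])
  rr <- row(base); cc <- col(base)
  spot <- matrix(0, dims[1], dims[2])
  for (k in seq_len(nrow(boutons))) {
    b <- boutons[k, ]
    spot <- spot + b$amp *
      exp(-((rr - b$row)^2 + (cc - b$col)^2) / (2 * b$sigma^2))
  }
  nfr <- length(frame_times)
  frames <- array(0, dim = c(dims[1], dims[2], nfr))
  noise <- if (noise_sd > 0)
    with_seed(seed, array(stats::rnorm(prod(dims) * nfr, 0, noise_sd),
                          dim = c(dims[1], dims[2], nfr)))
  else NULL
  for (i in seq_len(nfr)) {
    fr <- background + timecourse[i] * spot
    if (!is.null(noise)) fr <- fr + noise[, , i]
    frames[, , i] <- fr
  }
  structure(list(frames = frames, frame_times = frame_times),
            class = "image_stack")
}
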