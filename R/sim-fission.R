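#' Pore event specification
#'
#' Describes one exo- or endocytic capacitance event for the forward model: a
#' vesicle of capacitance `Cv` whose connection to the plasma membrane passes
#' through a narrow pore of conductance `Gp(t)` lasting `pore_duration`
#' seconds. `pore_duration = 0` gives an instantaneous capacitance step.
#'
#' For an endocytic event the vesicle is part of the patch membrane before
#' `t_start` (pore conductance effectively infinite) and detached afterwards
#' (`Gp = 0`); exocytic events run the other way. If no `Gp_profile` is given
#' a linear profile between `gp_start` and 0 (endocytic; reversed for
#' exocytic) is used.
#'
#' @param t_start event onset, seconds from trace start.
#' @param direction `"endocytic"` or `"exocytic"`.
#' @param Cv vesicle capacitance in farads.
#' @param pore_duration pore lifetime in seconds (0 = instantaneous step).
#' @param Gp_profile optional function of time-in-pore (seconds, on
#'   `[0, pore_duration]`) returning pore conductance in siemens.
#' @param gp_start pore conductance (siemens) at which the default linear
#'   profile starts (endocytic) or ends (exocytic).
#' @return an object of class `pore_event`.
#' @export
pore_event <- function(t_start, direction = c("endocytic", "exocytic"),
                       Cv, pore_duration = 0, Gp_profile = NULL,
                       gp_start = 2e-9) {
  direction <- match.arg(direction)
  stopifnot(Cv > 0, pore_duration >= 0, t_start >= 0, gp_start > 0)
  if (is.null(Gp_profile) && pore_duration > 0) {
    Gp_profile <- if (direction == "endocytic") {
      function(s) gp_start * pmax(0, 1 - s / pore_duration)
    } else {
      function(s) gp_start * pmin(1, s / pore_duration)
    }
  }
  structure(list(t_start = t_start, direction = direction, Cv = Cv,
                 pore_duration = pore_duration, Gp_profile = Gp_profile,
                 gp_start = gp_start),
            class = "pore_event")
}

#' Complex admittance of a vesicle connected through a pore
#'
#' For a vesicle of capacitance `Cv` behind a pore of conductance `Gp`, the
#' series combination gives
#' `Re(Y) = omega^2 Cv^2 Gp / (Gp^2 + omega^2 Cv^2)` and
#' `Im(Y) = omega Cv Gp^2 / (Gp^2 + omega^2 Cv^2)`.
#' As `Gp -> Inf` the admittance is purely capacitive (`Re = 0`,
#' `Im = omega*Cv`); as `Gp -> 0` both channels vanish.
#'
#' @param Gp pore conductance in siemens (vectorised; `Inf` allowed).
#' @param Cv vesicle capacitance in farads.
#' @param omega angular lock-in frequency in rad/s.
#' @return list with numeric vectors `Re` and `Im` (siemens).
#' @export
pore_admittance <- function(Gp, Cv, omega) {
  wc <- omega * Cv
  d <- Gp^2 + wc^2
  re <- wc^2 * Gp / d
  im <- wc * Gp^2 / d
  inf <- is.infinite(Gp)
  re[inf] <- 0
  im[inf] <- wc
  zero <- Gp == 0
  re[zero] <- 0
  im[zero] <- 0
  list(Re = re, Im = im)
}

#' Simulate a cell-attached lock-in admittance trace with pore events
#'
#' Forward model for the fission/fusion-pore analysis: each event contributes
#' the pore admittance of [pore_admittance()] to the Re/Im channels, on top of
#' constant baselines. The summed channels are passed through the lock-in
#' output filter and white Gaussian noise (`cfg$noise_sd`, siemens) is added
#' before filtering.
#'
#' @param events list of [pore_event()] specifications, non-overlapping in
#'   time.
#' @param cfg a [sim_config()]; `lockin_frequency` sets omega.
#' @param re_baseline,im_baseline constant baseline admittance (siemens).
#' @return list with `trace` (a `lockin_trace`) and `truth` (ground-truth
#'   event table plus per-event sampled pore profiles).
#' @export
simulate_fission_trace <- function(events, cfg,
                                   re_baseline = 0, im_baseline = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(events) > 0) {
    stopifnot(all(vapply(events, inherits, logical(1), "pore_event")))
    iv <- t(vapply(events, function(e)
      c(e$t_start, e$t_start + max(e$pore_duration, 0)), numeric(2)))
    o <- order(iv[, 1])
    iv <- iv[o, , drop = FALSE]
    events <- events[o]
    if (nrow(iv) > 1 && any(iv[-nrow(iv), 2] > iv[-1, 1]))
      stop("overlapping pore events: event intervals must be disjoint")
  }
  n <- round(cfg$sampling_rate * cfg$duration)
  tt <- (seq_len(n) - 1L) / cfg$sampling_rate
  omega <- 2 * pi * cfg$lockin_frequency
  re <- rep(re_baseline, n)
  im <- rep(im_baseline, n)
  truth_events <- list()
  for (e in events) {
    gp <- numeric(n)
    attached_before <- e$direction == "endocytic"
    pre <- tt < e$t_start
    post <- tt >= e$t_start + e$pore_duration
    in_pore <- !pre & !post
    gp[pre] <- if (attached_before) Inf else 0
    gp[post] <- if (attached_before) 0 else Inf
    if (any(in_pore)) gp[in_pore] <- e$Gp_profile(tt[in_pore] - e$t_start)
    y <- pore_admittance(gp, e$Cv, omega)
    re <- re + y$Re
    im <- im + y$Im
    truth_events[[length(truth_events) + 1L]] <- list(
      t_start = e$t_start, direction = e$direction, Cv = e$Cv,
      pore_duration = e$pore_duration,
      gp_samples = if (any(in_pore)) unname(gp[in_pore]) else numeric(0),
      gp_times = if (any(in_pore)) unname(tt[in_pore]) else numeric(0))
  }
  if (cfg$noise_sd > 0) {
    noise <- with_seed(cfg$seed, matrix(stats::rnorm(2 * n, 0, cfg$noise_sd), ncol = 2))
    re <- re + noise[, 1]
    im <- im + noise[, 2]
  }
  re <- lockin_filter(re, cfg)
  im <- lockin_filter(im, cfg)
  trace <- lockin_trace(time = tt, Re = re, Im = im,
                        sampling_rate = cfg$sampling_rate,
                        lockin_frequency = cfg$lockin_frequency)
  truth <- structure(list(kind = "fission", events = truth_events,
                          cfg = unclass(cfg)),
                     class = "ground_truth")
  list(trace = trace, truth = truth)
}

#' Lock-in admittance trace container
#'
#' @param time sample times, seconds, strictly increasing.
#' @param Re,Im real and imaginary admittance channels, siemens.
#' @param sampling_rate samples per second.
#' @param lockin_frequency carrier frequency, Hz.
#' @return an object of class `lockin_trace`. The capacitance display
#'   equivalent of the Im channel is `Im / (2*pi*lockin_frequency)`.
#' @export
lockin_trace <- function(time, Re, Im, sampling_rate, lockin_frequency) {
  stopifnot(length(time) == length(Re), length(Re) == length(Im),
            lockin_frequency > 0, all(diff(time) > 0))
  structure(list(time = time, Re = Re, Im = Im,
                 sampling_rate = sampling_rate,
                 lockin_frequency = lockin_frequency),
            class = "lockin_trace")
}

#' @export
print.lockin_trace <- function(x, ...) {
  cat("lockin_trace:", length(x$time), "samples,",
      x$sampling_rate, "Hz, carrier", x$lockin_frequency, "Hz\n")
  invisible(x)
}
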