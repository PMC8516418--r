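#' Pore conductance from both admittance channels
#'
#' For baseline-subtracted, event-attributable admittance the pore
#' conductance is `Gp = (Re^2 + Im^2) / Re`. Samples with `Re <= 0` (noise
#' crossing zero near pore closure, or a fully open pore where `Re -> 0+`)
#' are returned as `NA` rather than raising an error; if every sample has
#' `Re <= 0` the whole segment is rejected.
#'
#' @param Re,Im event-attributable real and imaginary admittance, siemens.
#' @return numeric vector of pore conductances, siemens (`NA` where
#'   undefined).
#' @seealso [gp_from_im()] for the single-channel estimate.
#' @export
gp_from_re_im <- function(Re, Im) {
  stopifnot(length(Re) == length(Im))
  if (all(Re <= 0, na.rm = TRUE))
    stop("Gp undefined: Re <= 0 over the whole segment")
  gp <- (Re^2 + Im^2) / Re
  gp[!is.na(Re) & Re <= 0] <- NA_real_
  gp
}

#' Pore conductance from the imaginary channel alone
#'
#' `Gp = omega*Cv / sqrt(omega*Cv/Im - 1)`, valid for `0 < Im < omega*Cv`.
#' `Im >= omega*Cv` is indistinguishable from a fully open pore and returns
#' `Inf`; `Im <= 0` means the pore has closed and returns `NA`.
#'
#' @param Im event-attributable imaginary admittance, siemens.
#' @param Cv vesicle capacitance, farads.
#' @param omega angular lock-in frequency, rad/s.
#' @return numeric vector of pore conductances, siemens.
#' @export
gp_from_im <- function(Im, Cv, omega) {
  stopifnot(Cv > 0, omega > 0)
  wc <- omega * Cv
  gp <- rep(NA_real_, length(Im))
  open <- !is.na(Im) & Im >= wc
  ok <- !is.na(Im) & Im > 0 & Im < wc
  gp[open] <- Inf
  gp[ok] <- wc / sqrt(wc / Im[ok] - 1)
  gp
}

#' Detect capacitance steps in a lock-in admittance trace
#'
#' Sliding two-window mean-difference statistic on the Im channel with a
#' robust (MAD-based) noise scale. A transition is reported when the absolute
#' window difference exceeds `max(min_step * omega, k * noise)`, where
#' `noise` is the robust SD of the statistic itself. Step size is measured
#' between pre- and post-transition plateaus (windows of `size_window`
#' seconds placed outside the detected transition), so slow pore closures
#' report the full capacitance change. Downward Im steps are endocytic,
#' upward exocytic.
#'
#' @param trace a [lockin_trace()].
#' @param min_step minimum reliable step size, farads (default 0.2 fF; steps
#'   below this are never returned).
#' @param min_separation minimum time between reported events, s.
#' @param window half-width of the sliding detection window, s.
#' @param size_window plateau length used for step-size estimation, s.
#' @param k noise multiple for the adaptive threshold component.
#' @return data.frame of class `capacitance_events` with one row per event:
#'   `t_step` (transition midpoint, s), `direction`, `Cv` (farads),
#'   `i_start`, `i_end` (sample indices bracketing the transition), and
#'   placeholders for pore kinetics (`fission_pore_duration`, `Gp_mean`,
#'   `kinetics_valid`), filled by [measure_fission_pore()].
#' @export
detect_capacitance_steps <- function(trace, min_step = 0.2e-15,
                                     min_separation = 0.25,
                                     window = 0.02, size_window = 0.1,
                                     k = 3) {
  stopifnot(inherits(trace, "lockin_trace"), min_step > 0)
  fs <- trace$sampling_rate
  omega <- 2 * pi * trace$lockin_frequency
  im <- trace$Im
  n <- length(im)
  w <- max(5L, round(window * fs))
  if (n < 4L * w) stop("trace shorter than the detection window")
  # two-window mean difference d[i] = mean(im[i+1..i+w]) - mean(im[i-w+1..i])
  cs <- cumsum(im)
  i <- w:(n - w)
  d <- (cs[i + w] - cs[i]) / w - (cs[i] - c(0, cs)[i - w + 1]) / w
  sigma_d <- stats::mad(d, na.rm = TRUE)
  thr <- max(min_step * omega, k * sigma_d)
  above <- abs(d) >= thr
  if (!any(above)) return(empty_events())
  # contiguous suprathreshold runs at half threshold, seeded by full-threshold
  runs <- rle(abs(d) >= thr / 2)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- list()
  for (j in which(runs$values)) {
    seg <- starts[j]:ends[j]
    if (!any(above[seg])) next
    peak <- seg[which.max(abs(d[seg]))]
    cand[[length(cand) + 1L]] <- list(stat = abs(d[peak]),
                                      center = peak + w - 1L,
                                      run = c(starts[j], ends[j]) + w - 1L)
  }
  if (!length(cand)) return(empty_events())
  # enforce min_separation, keeping the larger statistic
  cand <- cand[order(-vapply(cand, `[[`, numeric(1), "stat"))]
  kept <- list()
  for (c1 in cand) {
    tc <- trace$time[c1$center]
    if (all(vapply(kept, function(c2)
      abs(trace$time[c2$center] - tc) >= min_separation, logical(1))))
      kept[[length(kept) + 1L]] <- c1
  }
  kept <- kept[order(vapply(kept, `[[`, numeric(1), "center"))]
  ws <- max(5L, round(size_window * fs))
  rows <- lapply(kept, function(c1) {
    i0 <- c1$run[1]; i1 <- c1$run[2]
    pre_idx <- max(1L, i0 - ws):max(1L, i0 - 1L)
    post_idx <- min(n, i1 + 1L):min(n, i1 + ws)
    pre <- mean(im[pre_idx]); post <- mean(im[post_idx])
    size <- abs(post - pre) / omega
    if (size < min_step) return(NULL)
    # transition midpoint: crossing of the half level
    mid <- (pre + post) / 2
    seg <- i0:i1
    crossed <- if (post < pre) im[seg] <= mid else im[seg] >= mid
    i_mid <- if (any(crossed)) seg[which(crossed)[1]] else c1$center
    data.frame(t_step = trace$time[i_mid],
               direction = if (post < pre) "endocytic" else "exocytic",
               Cv = size, i_start = i0, i_end = i1,
               fission_pore_duration = NA_real_, Gp_mean = NA_real_,
               kinetics_valid = NA, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_events())
  out <- do.call(rbind, rows)
  class(out) <- c("capacitance_events", "data.frame")
  out
}

empty_events <- function() {
  out <- data.frame(t_step = numeric(0), direction = character(0),
                    Cv = numeric(0), i_start = integer(0),
                    i_end = integer(0),
                    fission_pore_duration = numeric(0),
                    Gp_mean = numeric(0), kinetics_valid = logical(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("capacitance_events", "data.frame")
  out
}

#' Measure fission-pore duration and mean conductance for one event
#'
#' The pore window is bounded by the conductance thresholds `g_on` (pore
#' becomes measurable) and `g_off` (closure), applied through the real
#' admittance channel: the event-attributable Re rises from 0 as the pore
#' conductance falls to `g_on` (`Re(g_on) = omega^2 Cv^2 g_on /
#' (g_on^2 + omega^2 Cv^2)`), peaks at `omega Cv / 2` mid-pore, and falls
#' back through `Re(g_off)` at closure. Re is used for the timing because
#' near pore onset Im sits within a fraction of a percent of its plateau,
#' whereas the Re deflections at both thresholds are large compared with
#' recording noise; the thresholds are additionally floored at 4 x the
#' pre-event noise SD. `Gp_mean` is the mean single-channel estimate
#' ([gp_from_im()], using the event's Cv) over the window. Kinetics are
#' valid only for durations exceeding 15 ms -- shorter pores are distorted
#' by the 1 ms lock-in output filter and are flagged, never reported as
#' valid.
#'
#' @param trace a [lockin_trace()].
#' @param event one row of the table returned by
#'   [detect_capacitance_steps()].
#' @param g_on conductance at which the pore becomes measurable, siemens.
#' @param g_off conductance taken as closure, siemens.
#' @param min_valid_duration validity threshold, s (default 0.015).
#' @return list with `duration` (s), `Gp_mean` (siemens), and
#'   `kinetics_valid`.
#' @export
measure_fission_pore <- function(trace, event, g_on = 2e-9, g_off = 10e-12,
                                 min_valid_duration = 0.015) {
  stopifnot(inherits(trace, "lockin_trace"), g_on > g_off, g_off > 0)
  omega <- 2 * pi * trace$lockin_frequency
  fs <- trace$sampling_rate
  n <- length(trace$Im)
  Cv <- event$Cv
  wc <- omega * Cv
  pad <- max(5L, round(0.15 * fs))   # covers slow (~100 ms) pores
  endo <- event$direction == "endocytic"
  i0 <- max(1L, event$i_start - pad)
  i1 <- min(n, event$i_end + pad)
  seg <- i0:i1
  # Re baseline and noise from the pre-event side of the segment
  pre_idx <- max(1L, i0 - pad):max(1L, i0 - 1L)
  re_base <- mean(trace$Re[pre_idx])
  sigma_re <- stats::sd(trace$Re[pre_idx])
  re_v <- trace$Re[seg] - re_base
  # Im zero level on the detached side, for the Gp_mean estimate
  im_plateau_idx <- if (endo)
    min(n, event$i_end + 1L):min(n, event$i_end + pad)
  else
    max(1L, event$i_start - pad):max(1L, event$i_start - 1L)
  im_v <- trace$Im[seg] - mean(trace$Im[im_plateau_idx])
  if (!endo) {                    # analyse exocytic pores time-reversed
    re_v <- rev(re_v)
    im_v <- rev(im_v)
  }
  # onset is a step-like Re deflection (the pore forms abruptly at g_on):
  # time it at the half level of Re(g_on), the unbiased convention for a
  # low-pass-filtered step; closure is a ramp crossing, timed at Re(g_off)
  re_on <- wc^2 * g_on / (g_on^2 + wc^2) / 2
  re_off <- wc^2 * g_off / (g_off^2 + wc^2)
  if (is.finite(sigma_re)) {
    re_on <- max(re_on, 4 * sigma_re)
    re_off <- max(re_off, 4 * sigma_re)
  }
  first_sustained <- function(cond, run = 3L) {
    r <- rle(cond)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    hit <- which(r$values & r$lengths >= run)
    if (length(hit)) s[hit[1]] else NA_integer_
  }
  k_on <- first_sustained(re_v >= re_on)
  if (is.na(k_on))
    return(list(duration = 0, Gp_mean = NA_real_, kinetics_valid = FALSE))
  k_pk <- (k_on - 1L) + which.max(re_v[k_on:length(re_v)])
  k_off <- first_sustained(re_v <= re_off & seq_along(re_v) >= k_pk)
  if (is.na(k_off)) k_off <- length(re_v)
  duration <- (k_off - k_on) / fs
  gp_win <- if (k_off > k_on) im_v[k_on:(k_off - 1L)] else numeric(0)
  gp <- gp_from_im(gp_win, Cv, omega)
  gp <- gp[is.finite(gp)]
  list(duration = duration,
       Gp_mean = if (length(gp)) mean(gp) else NA_real_,
       kinetics_valid = duration > min_valid_duration)
}

#' Annotate detected events with pore kinetics
#'
#' Convenience wrapper applying [measure_fission_pore()] to every event in a
#' detection table.
#'
#' @inheritParams measure_fission_pore
#' @param events table from [detect_capacitance_steps()].
#' @return the events table with `fission_pore_duration`, `Gp_mean`, and
#'   `kinetics_valid` filled in.
#' @export
measure_all_pores <- function(trace, events, g_on = 2e-9, g_off = 10e-12,
                              min_valid_duration = 0.015) {
  for (i in seq_len(nrow(events))) {
    m <- measure_fission_pore(trace, events[i, ], g_on, g_off,
                              min_valid_duration)
    events$fission_pore_duration[i] <- m$duration
    events$Gp_mean[i] <- m$Gp_mean
    events$kinetics_valid[i] <- m$kinetics_valid
  }
  events
}

#' Count endocytic events within a recording window
#'
#' The per-patch event count is the number of downward capacitance steps
#' with `t_step` at or before `window` seconds from the recording start
#' (default 300 s, i.e. the first 5 minutes).
#'
#' @param events table from [detect_capacitance_steps()].
#' @param window counting window, s.
#' @return integer count.
#' @export
count_endocytic_events <- function(events, window = 300) {
  if (nrow(events) == 0) return(0L)
  sum(events$direction == "endocytic" & events$t_step <= window)
}
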