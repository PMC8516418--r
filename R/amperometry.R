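#' Baseline model for an amperometric trace
#'
#' Median level of the pre-stimulus segment with slow drift removed by a
#' first-order (linear) fit; the fitted line is extrapolated over the whole
#' trace. Returns the per-sample baseline and the residual SD of the
#' pre-stimulus segment.
#'
#' @param trace an [amperometric_trace()].
#' @param pre_len length of pre-stimulus segment used, s.
#' @return list with `level` (numeric vector, pA) and `sd` (pA).
#' @keywords internal
amp_baseline <- function(trace, pre_len = 5) {
  pre <- trace$time < trace$stim_time &
    trace$time >= trace$stim_time - pre_len
  if (sum(pre) < 10)
    stop("no usable pre-stimulus baseline segment")
  fit <- stats::lm(I ~ t, data = data.frame(t = trace$time[pre],
                                            I = trace$I[pre]))
  level <- unname(stats::coef(fit)[1] + stats::coef(fit)[2] * trace$time)
  list(level = level, sd = stats::sd(stats::resid(fit)))
}

#' Detect amperometric spikes
#'
#' Single-spike analysis criteria: only spikes whose baseline-subtracted
#' peak exceeds `min_amp` (default 10 pA) are considered, and at most
#' `max_per_cell` spikes (default 100, earliest first) are analyzed per
#' cell. Candidate events are contiguous suprathreshold regions of the
#' baseline-subtracted current; each contributes one spike at its maximum.
#' Spikes whose half-maximum extents touch are flagged `overlapping` and are
#' excluded from shape statistics (but still counted for frequency).
#'
#' @param trace an [amperometric_trace()].
#' @param min_amp amplitude criterion, pA.
#' @param max_per_cell cap on analyzed spikes.
#' @param pre_len baseline segment length, s.
#' @param min_gap minimum gap between distinct events, s.
#' @return data.frame of class `amperometric_spikes`: `t_peak` (s), `peak`
#'   (pA), `i_peak`, `i_start`, `i_end` (indices of the suprathreshold
#'   region), `overlapping`, `included`.
#' @export
detect_spikes <- function(trace, min_amp = 10, max_per_cell = 100,
                          pre_len = 5, min_gap = 0.002) {
  stopifnot(inherits(trace, "amperometric_trace"), min_amp > 0)
  bl <- amp_baseline(trace, pre_len)
  y <- trace$I - bl$level
  # lightly smoothed copy for the amplitude criterion, so the threshold is
  # applied to the spike rather than to single noise excursions
  wsm <- max(1L, round(6e-4 * trace$sampling_rate))
  ysm <- if (wsm > 1)
    as.numeric(stats::filter(y, rep(1 / wsm, wsm), sides = 2))
  else y
  ysm[is.na(ysm)] <- 0
  thr <- max(3 * bl$sd, 0.1 * min_amp)
  above <- y > thr
  if (!any(above)) return(empty_spikes())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge segments separated by less than min_gap
  gap <- round(min_gap * trace$sampling_rate)
  if (nrow(seg) > 1) {
    keep <- rep(TRUE, nrow(seg))
    for (i in 2:nrow(seg)) {
      j <- max(which(keep[1:(i - 1)]))
      if (seg$start[i] - seg$end[j] <= gap) {
        seg$end[j] <- seg$end[i]
        keep[i] <- FALSE
      }
    }
    seg <- seg[keep, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(seg)), function(i) {
    idx <- seg$start[i]:seg$end[i]
    ip <- idx[which.max(y[idx])]
    pk <- y[ip]
    # amplitude criterion with a noise guard: the smoothed peak must clear
    # the threshold by 3 baseline SDs, so noise cannot promote a
    # subthreshold spike
    if (pk <= min_amp || max(ysm[idx]) <= min_amp + 3 * bl$sd) return(NULL)
    data.frame(t_peak = trace$time[ip], peak = pk, i_peak = ip,
               i_start = seg$start[i], i_end = seg$end[i],
               overlapping = FALSE, included = TRUE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_spikes())
  out <- do.call(rbind, rows)
  out <- out[order(out$t_peak), , drop = FALSE]
  # overlap at half-max: half-max extents of neighbours touching
  if (nrow(out) > 1) {
    for (i in seq_len(nrow(out) - 1)) {
      half_i <- out$peak[i] / 2
      half_j <- out$peak[i + 1] / 2
      iright <- out$i_peak[i]
      while (iright < length(y) && y[iright] > half_i) iright <- iright + 1L
      jleft <- out$i_peak[i + 1]
      while (jleft > 1 && y[jleft] > half_j) jleft <- jleft - 1L
      if (iright >= jleft) out$overlapping[c(i, i + 1)] <- TRUE
    }
  }
  if (nrow(out) > max_per_cell) out <- out[seq_len(max_per_cell), ]
  rownames(out) <- NULL
  attr(out, "baseline") <- bl
  class(out) <- c("amperometric_spikes", "data.frame")
  out
}

empty_spikes <- function() {
  out <- data.frame(t_peak = numeric(0), peak = numeric(0),
                    i_peak = integer(0), i_start = integer(0),
                    i_end = integer(0), overlapping = logical(0),
                    included = logical(0))
  class(out) <- c("amperometric_spikes", "data.frame")
  out
}

#' Quantify one amperometric spike
#'
#' Returns the classic single-spike parameters: `peak` (baseline-subtracted
#' maximum, pA), `halfwidth` (full width at half maximum, ms, by linear
#' interpolation of the half-level crossings), `tau_decay` (ms, log-linear
#' fit of the falling phase between 75% and 25% of the peak), and
#' `quantal_size` (pC, trapezoidal integral of the baseline-subtracted
#' current over the spike extent: from the suprathreshold departure to the
#' first return within one baseline SD, or 0.2% of peak when noiseless).
#'
#' @param trace an [amperometric_trace()].
#' @param spike one row of [detect_spikes()] output.
#' @param pre_len baseline segment length, s.
#' @return list with `peak`, `halfwidth`, `tau_decay`, `quantal_size`.
#' @export
spike_params <- function(trace, spike, pre_len = 5) {
  bl <- amp_baseline(trace, pre_len)
  y <- trace$I - bl$level
  tt <- trace$time
  ip <- spike$i_peak
  pk <- y[ip]
  half <- pk / 2
  # half-max crossings by interpolation
  i <- ip
  while (i > 1 && y[i - 1] > half) i <- i - 1L
  t_left <- if (i == 1) tt[1] else
    tt[i - 1] + (tt[i] - tt[i - 1]) * (half - y[i - 1]) / (y[i] - y[i - 1])
  j <- ip
  while (j < length(y) && y[j + 1] > half) j <- j + 1L
  t_right <- if (j == length(y)) tt[j] else
    tt[j] + (tt[j + 1] - tt[j]) * (y[j] - half) / (y[j] - y[j + 1])
  halfwidth <- (t_right - t_left) * 1e3
  # falling phase 75% -> 25% of peak, bounded by the first threshold
  # crossings (a contiguous window, so noise cannot cherry-pick samples)
  imax <- min(length(y), spike$i_end + round(0.05 * trace$sampling_rate))
  i75 <- ip
  while (i75 < imax && y[i75] > 0.75 * pk) i75 <- i75 + 1L
  i25 <- i75
  while (i25 < imax && y[i25] > 0.25 * pk) i25 <- i25 + 1L
  tau_decay <- if (i25 - i75 >= 3L) {
    fall <- i75:i25
    f <- fit_exponential(tt[fall], y[fall], tt[i75], offset = FALSE)
    f$tau * 1e3
  } else NA_real_
  # spike extent for charge: to the first sustained return to baseline
  floor_lvl <- max(bl$sd, 0.002 * pk)
  a <- spike$i_start
  below <- y <= floor_lvl & seq_along(y) > ip
  run <- 5L
  b <- length(y)
  cs <- cumsum(below)
  for (j in which(below)) {
    if (j + run - 1L <= length(y) && cs[j + run - 1L] - cs[j - 1L] == run) {
      b <- j
      break
    }
  }
  quantal_size <- trapz(tt[a:b], y[a:b])
  list(peak = pk, halfwidth = halfwidth, tau_decay = tau_decay,
       quantal_size = quantal_size)
}

#' Detect the pre-spike foot
#'
#' The foot starts at the first sustained departure of the current above
#' baseline + 3 SD preceding the spike, and ends at the spike onset, defined
#' by back-extrapolating the maximal-slope line of the rising phase down to
#' the foot current level. Feet shorter than `min_foot_ms` are excluded from
#' foot statistics; absence of a foot is a valid outcome, not an error.
#'
#' @param trace an [amperometric_trace()].
#' @param spike one row of [detect_spikes()] output.
#' @param min_foot_ms minimum counted foot duration, ms.
#' @param pre_len baseline segment length, s.
#' @return list with `foot_duration` (ms), `foot_amp` (pA), `excluded`
#'   (TRUE when a foot was found but is shorter than `min_foot_ms`), or
#'   `NULL` when no foot is resolvable.
#' @export
detect_foot <- function(trace, spike, min_foot_ms = 0.5, pre_len = 5) {
  bl <- amp_baseline(trace, pre_len)
  y <- trace$I - bl$level
  tt <- trace$time
  fs <- trace$sampling_rate
  ip <- spike$i_peak
  pk <- y[ip]
  thr <- max(3 * bl$sd, 0.002 * pk)
  # first sustained departure above threshold, scanning back from the rise
  i <- ip
  while (i > 1 && y[i - 1] > thr) i <- i - 1L
  i_start <- i
  # maximal slope on the rising phase
  rise <- i_start:ip
  if (length(rise) < 3) return(NULL)
  slope <- diff(y[rise]) * fs
  im <- which.max(slope)
  s_max <- slope[im]
  i_ms <- rise[im]
  if (s_max <= 0) return(NULL)
  # foot level: median current between departure and where the fast rise
  # takes off (25% of peak)
  pre_rise <- y[i_start:ip]
  below <- which(pre_rise < 0.25 * pk)
  foot_level <- if (length(below) >= 2) stats::median(pre_rise[below]) else
    y[i_start]
  y_ms <- (y[i_ms] + y[i_ms + 1]) / 2
  t_ms <- (tt[i_ms] + tt[i_ms + 1]) / 2
  t_onset <- t_ms - (y_ms - foot_level) / s_max
  foot_duration <- (t_onset - tt[i_start]) * 1e3
  if (foot_duration <= 0) return(NULL)
  list(foot_duration = foot_duration,
       foot_amp = foot_level,
       excluded = foot_duration < min_foot_ms)
}

#' Spike frequency after stimulation
#'
#' Number of detected spikes (amplitude criterion already applied by
#' [detect_spikes()]) peaking within `window` seconds after `stim_time`.
#'
#' @param spikes [detect_spikes()] output.
#' @param stim_time stimulation time, s.
#' @param window counting window, s (default 15).
#' @return integer count.
#' @export
spike_frequency <- function(spikes, stim_time, window = 15) {
  if (nrow(spikes) == 0) return(0L)
  sum(spikes$t_peak >= stim_time & spikes$t_peak <= stim_time + window)
}

#' Per-cell median summary of spike parameters
#'
#' Medians are computed over included, non-overlapping spikes only;
#' statistics are later taken across cells, so the cell (not the spike) is
#' the unit of replication.
#'
#' @param params data.frame with one row per analyzed spike (columns `peak`,
#'   `halfwidth`, `tau_decay`, `quantal_size`, optionally `foot_duration`)
#'   for one cell.
#' @param cell_id identifier.
#' @param n_spikes_15s spike count in the 15 s post-stimulus window
#'   (from [spike_frequency()]), optional.
#' @return one-row data.frame of class `cell_summary`.
#' @export
cell_summary <- function(params, cell_id, n_spikes_15s = NA_integer_) {
  params <- as.data.frame(params)
  if (nrow(params) == 0) {
    warning("cell ", cell_id, " has no included spikes; excluded")
    return(NULL)
  }
  med <- function(v) if (is.null(v)) NA_real_ else
    stats::median(v, na.rm = TRUE)
  out <- data.frame(cell_id = cell_id, n_spikes = nrow(params),
                    spike_frequency = n_spikes_15s,
                    peak = med(params$peak),
                    halfwidth = med(params$halfwidth),
                    tau_decay = med(params$tau_decay),
                    quantal_size = med(params$quantal_size),
                    foot_duration = med(params$foot_duration))
  class(out) <- c("cell_summary", "data.frame")
  out
}

#' Group summary: mean +/- SEM of the cell medians
#'
#' @param cells data.frame of row-bound [cell_summary()] results.
#' @return data.frame with one row per parameter: `mean`, `sem`, `n_cells`.
#' @export
group_summary <- function(cells) {
  cells <- as.data.frame(cells)
  pars <- c("peak", "halfwidth", "tau_decay", "quantal_size",
            "foot_duration", "spike_frequency")
  do.call(rbind, lapply(pars, function(p) {
    v <- cells[[p]]
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(parameter = p,
               mean = if (n) mean(v) else NA_real_,
               sem = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_,
               n_cells = n)
  }))
}
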