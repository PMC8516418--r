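#' Measure the endocytosis-associated current drift for one event
#'
#' Fits straight lines to a pre-event and a post-event window of the patch
#' current (window lengths between 20 and 100 ms), each separated from the
#' event by a guard gap that excludes the filtered transition, and reports
#' the difference of the two fits extrapolated to the event time.
#' Extrapolating both fits to `t_event` (rather than differencing window
#' means) makes the estimate exact for any shared baseline slope.
#'
#' @param trace a [patch_current_trace()].
#' @param t_event capacitance-drop time, s (defaults to the trace's linked
#'   event time).
#' @param pre_len,post_len fit-window lengths, s; must lie in `[0.02, 0.1]`.
#' @param guard guard gap on each side of `t_event`, s.
#' @return an object of class `drift_measurement`: list with `V_patch` (mV),
#'   `delta_I` (pA, post minus pre at `t_event`), per-window `r2`, and the
#'   window definitions.
#' @export
measure_current_drift <- function(trace, t_event = trace$t_event,
                                  pre_len = 0.08, post_len = 0.08,
                                  guard = 0.010) {
  stopifnot(inherits(trace, "patch_current_trace"), is.finite(t_event))
  if (pre_len < 0.02 || pre_len > 0.1 || post_len < 0.02 || post_len > 0.1)
    stop("fit-window lengths must be between 20 and 100 ms")
  tt <- trace$time
  pre_idx <- tt >= t_event - guard - pre_len & tt < t_event - guard
  post_idx <- tt > t_event + guard & tt <= t_event + guard + post_len
  if (sum(pre_idx) < 5 || sum(post_idx) < 5)
    stop("insufficient samples in the fit windows")
  fit <- function(idx) {
    m <- stats::lm(I ~ t, data = data.frame(t = tt[idx] - t_event,
                                            I = trace$I[idx]))
    ss_tot <- sum((trace$I[idx] - mean(trace$I[idx]))^2)
    r2 <- if (ss_tot > 0) 1 - sum(stats::resid(m)^2) / ss_tot else 1
    list(at_event = unname(stats::coef(m)[1]), r2 = r2)
  }
  pre <- fit(pre_idx)
  post <- fit(post_idx)
  structure(list(V_patch = trace$V_patch,
                 delta_I = post$at_event - pre$at_event,
                 r2_pre = pre$r2, r2_post = post$r2,
                 fit_window_pre = c(t_event - guard - pre_len,
                                    t_event - guard),
                 fit_window_post = c(t_event + guard,
                                     t_event + guard + post_len)),
            class = "drift_measurement")
}

#' Assemble a current-voltage relationship from drift measurements
#'
#' Groups drift measurements by patch voltage and reports mean, SEM, and n
#' per voltage, sorted by ascending voltage.
#'
#' @param measurements list of [measure_current_drift()] results (or a
#'   data.frame with columns `V_patch`, `delta_I`).
#' @return data.frame of class `iv_curve` with columns `V_patch` (mV),
#'   `mean_delta_I`, `sem`, `n`.
#' @export
build_iv <- function(measurements) {
  if (inherits(measurements, "drift_measurement"))
    measurements <- list(measurements)
  if (is.data.frame(measurements)) {
    df <- measurements[, c("V_patch", "delta_I")]
  } else {
    if (!length(measurements)) stop("no drift measurements supplied")
    df <- data.frame(
      V_patch = vapply(measurements, `[[`, numeric(1), "V_patch"),
      delta_I = vapply(measurements, `[[`, numeric(1), "delta_I"))
  }
  if (!nrow(df)) stop("no drift measurements supplied")
  agg <- do.call(rbind, lapply(split(df, df$V_patch), function(g) {
    n <- nrow(g)
    data.frame(V_patch = g$V_patch[1], mean_delta_I = mean(g$delta_I),
               sem = if (n > 1) stats::sd(g$delta_I) / sqrt(n) else NA_real_,
               n = n)
  }))
  agg <- agg[order(agg$V_patch), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("iv_curve", "data.frame")
  agg
}

#' Linearity and rectification of a drift current-voltage relationship
#'
#' A pure loss of non-specific leak channels predicts a linear I-V; a
#' voltage-dependent (e.g. outwardly rectifying) conductance loss does not.
#' `linear_r2` is the R-squared of an ordinary least-squares line through the
#' IV points; `rectification_index` is the magnitude of the mean drift at the
#' most positive voltage divided by that at the most negative voltage
#' (about 1 for an ohmic loss, substantially above 1 for an outward
#' rectifier).
#'
#' @param iv an [build_iv()] result spanning at least 3 voltages including
#'   both signs.
#' @return list with `linear_r2` and `rectification_index` (`NA` with a
#'   warning if the drift at the most negative voltage is 0).
#' @export
rectification_test <- function(iv) {
  stopifnot(inherits(iv, "iv_curve"))
  if (nrow(iv) < 3 || min(iv$V_patch) >= 0 || max(iv$V_patch) <= 0)
    stop("IV curve must span at least 3 voltages including negative and positive values")
  m <- stats::lm(mean_delta_I ~ V_patch, data = iv)
  ss_tot <- sum((iv$mean_delta_I - mean(iv$mean_delta_I))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(m)^2) / ss_tot else 1
  num <- abs(iv$mean_delta_I[which.max(iv$V_patch)])
  den <- abs(iv$mean_delta_I[which.min(iv$V_patch)])
  idx <- if (den == 0) {
    warning("flat IV at the most negative voltage: rectification index undefined")
    NA_real_
  } else num / den
  list(linear_r2 = r2, rectification_index = idx)
}
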