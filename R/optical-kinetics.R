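#' Extract ROI time series from an image stack
#'
#' Computes the per-frame mean intensity over each ROI. ROIs are either
#' 4 x 4 pixel boxes centred on bouton coordinates (the manual-placement
#' convention) or arbitrary logical masks (the automatic iGluSnFR
#' convention). When a background ROI is supplied its series is subtracted
#' frame by frame.
#'
#' @param stack an `image_stack` (see [simulate_image_stack()] /
#'   [read_image_stack()]).
#' @param rois either a data.frame with columns `row`, `col` (box centres)
#'   or a list of logical masks matching the frame size.
#' @param box box side length in pixels for centre-based ROIs.
#' @param background optional background ROI (one `c(row, col)` centre or a
#'   logical mask).
#' @param stim optional [stim_protocol()] attached to each series.
#' @return list of [roi_timeseries()], one per ROI.
#' @export
extract_roi_timeseries <- function(stack, rois, box = 4L,
                                   background = NULL, stim = NULL) {
  dims <- dim(stack$frames)[1:2]
  box_mask <- function(center) {
    r0 <- floor(center[1] - box / 2) + 1L
    c0 <- floor(center[2] - box / 2) + 1L
    if (r0 < 1 || c0 < 1 || r0 + box - 1L > dims[1] || c0 + box - 1L > dims[2])
      stop("ROI box extends beyond the frame bounds")
    m <- matrix(FALSE, dims[1], dims[2])
    m[r0:(r0 + box - 1L), c0:(c0 + box - 1L)] <- TRUE
    m
  }
  masks <- if (is.data.frame(rois)) {
    lapply(seq_len(nrow(rois)), function(i)
      box_mask(c(rois$row[i], rois$col[i])))
  } else {
    lapply(rois, function(m) {
      stopifnot(is.logical(m), all(dim(m) == dims))
      m
    })
  }
  series_of <- function(mask) {
    idx <- which(mask)
    vapply(seq_len(dim(stack$frames)[3]), function(k) {
      fr <- stack$frames[, , k]
      mean(fr[idx])
    }, numeric(1))
  }
  bg <- if (is.null(background)) NULL else if (is.matrix(background))
    series_of(background) else series_of(box_mask(background))
  lapply(masks, function(m) {
    F <- series_of(m)
    if (!is.null(bg)) F <- F - bg
    roi_timeseries(time = stack$frame_times, F = F, stim = stim)
  })
}

#' Automatic ROI detection for iGluSnFR stacks
#'
#' Difference image = mean of the response frames minus mean of the
#' pre-stimulus frames, thresholded at its mean + `k` SD; connected
#' components with strictly more than `min_area` pixels become ROIs. An
#' empty ROI set (no suprathreshold pixels or no sufficiently large
#' component) is a valid outcome.
#'
#' @param stack an `image_stack`.
#' @param stim a [stim_protocol()]; pre-stimulus frames are those before
#'   `stim$onset`, response frames those within the train plus
#'   `response_pad` seconds.
#' @param min_area minimum component area, pixels (strict inequality).
#' @param k threshold in SD units of the difference image.
#' @param response_pad seconds after the last stimulus still counted as
#'   response.
#' @return list of logical ROI masks (possibly empty), with component areas
#'   as the `areas` attribute.
#' @export
detect_iglusnfr_rois <- function(stack, stim, min_area = 10, k = 3,
                                 response_pad = 0.5) {
  tt <- stack$frame_times
  pre <- tt < stim$onset
  resp <- tt >= stim$onset & tt <= stim$end + response_pad
  if (!any(pre) || !any(resp))
    stop("stack must span pre-stimulus and response frames")
  mean_frames <- function(sel) {
    apply(stack$frames[, , sel, drop = FALSE], c(1, 2), mean)
  }
  diff_img <- mean_frames(resp) - mean_frames(pre)
  thr <- mean(diff_img) + k * stats::sd(diff_img)
  mask <- diff_img > thr
  if (!any(mask)) return(structure(list(), areas = integer(0)))
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  areas <- table(lab[lab > 0])
  keep <- as.integer(names(areas)[areas > min_area])
  rois <- lapply(keep, function(id) lab == id)
  structure(rois, areas = as.integer(areas[as.character(keep)]))
}

#' Normalize an ROI fluorescence series
#'
#' `dF = F - F0` with `F0` the pre-stimulus baseline mean. Mode
#' `"dF_over_dFmax"` divides by the post-onset peak of dF (pHluorin and
#' iGluSnFR convention: peak = 1); `"dF_over_F0"` divides by `F0` (GCaMP
#' convention). Normalizing an already-normalized series is a no-op.
#'
#' @param series a [roi_timeseries()].
#' @param mode `"dF_over_dFmax"` or `"dF_over_F0"`.
#' @return a normalized [roi_timeseries()] (the `F` field holds the
#'   normalized values).
#' @export
normalize_response <- function(series,
                               mode = c("dF_over_dFmax", "dF_over_F0")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "roi_timeseries"))
  if (identical(series$normalization, mode)) return(series)
  if (series$normalization != "none")
    stop("series already normalized with a different mode")
  if (is.null(series$F0) || is.na(series$F0))
    stop("series has no pre-stimulus baseline (F0)")
  dF <- series$F - series$F0
  if (mode == "dF_over_F0") {
    if (series$F0 <= 0) stop("F0 must be positive for dF/F0")
    out <- dF / series$F0
  } else {
    post <- if (!is.null(series$stim)) series$time >= series$stim$onset else
      rep(TRUE, length(dF))
    dFmax <- max(dF[post])
    if (dFmax <= 0) {
      if (all(dF == 0)) dFmax <- 1  # flat series normalizes to all zeros
      else stop("dFmax must be positive for dF/dFmax")
    }
    out <- dF / dFmax
  }
  series$F <- out
  series$normalization <- mode
  series
}

# Single-exponential fit y = A exp(-(t - t0)/tau) + C via nlsLM with
# log-linear initialisation. offset = FALSE fixes C = 0.
fit_exponential <- function(t, y, t0, offset = TRUE) {
  stopifnot(length(t) == length(y), length(y) >= 4)
  ts <- t - t0
  C0 <- if (offset) min(y) else 0
  A0 <- max(y[1] - C0, 1e-12)
  pos <- y - C0 > A0 * 0.05
  tau0 <- if (sum(pos) >= 3) {
    sl <- unname(stats::coef(stats::lm(log(y[pos] - C0 + A0 * 1e-6) ~
                                         ts[pos]))[2])
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(ts)) / 3
  } else diff(range(ts)) / 3
  tau0 <- min(max(tau0, 1e-6), diff(range(ts)) * 100)
  df <- data.frame(ts = ts, y = y)
  one_fit <- function(sA, stau, sC) tryCatch({
    if (offset)
      minpack.lm::nlsLM(y ~ A * exp(-ts / tau) + C, data = df,
                        start = list(A = sA, tau = stau, C = sC),
                        lower = c(-Inf, 1e-9, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ A * exp(-ts / tau), data = df,
                        start = list(A = sA, tau = stau),
                        lower = c(-Inf, 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  # retry from perturbed starts: the LM solver can report a singular
  # gradient from some exact start configurations on noiseless data
  fit <- one_fit(A0, tau0, C0)
  if (is.null(fit)) fit <- one_fit(A0 * 1.05, tau0 * 1.3, C0 - 0.05 * A0)
  if (is.null(fit)) fit <- one_fit(A0 * 0.9, tau0 * 0.7, C0 + 0.02 * A0)
  if (is.null(fit)) {
    fml <- if (offset) y ~ A * exp(-ts / tau) + C else y ~ A * exp(-ts / tau)
    st <- if (offset) list(A = A0, tau = tau0, C = C0) else
      list(A = A0, tau = tau0)
    lw <- if (offset) c(-Inf, 1e-9, -Inf) else c(-Inf, 1e-9)
    fit <- tryCatch(stats::nls(fml, data = df, start = st, lower = lw,
                               algorithm = "port"),
                    error = function(e) NULL)
  }
  if (is.null(fit))
    return(list(tau = NA_real_, amplitude = NA_real_, offset = NA_real_,
                r2 = NA_real_, flagged = TRUE))
  cf <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  flagged <- cf[["A"]] <= 0 || cf[["tau"]] > 50 * diff(range(ts))
  list(tau = unname(cf[["tau"]]), amplitude = unname(cf[["A"]]),
       offset = if (offset) unname(cf[["C"]]) else 0,
       r2 = r2, flagged = flagged)
}

#' Fit the endocytic time constant of a post-stimulus fluorescence decay
#'
#' Single-exponential fit `dF(t) = A exp(-(t - fit_start)/tau) + C` over the
#' post-stimulus samples of a normalized pHluorin series. The offset C is
#' free because endocytosis can be incomplete (the series plateaus above
#' baseline). Non-decaying series (A <= 0 or tau at the bound) are flagged.
#'
#' @param series a normalized [roi_timeseries()].
#' @param fit_start start of the decay fit, s (default: stimulus end).
#' @return list with `tau` (s), `amplitude`, `offset`, `r2`, `flagged`.
#' @export
fit_endocytic_tau <- function(series, fit_start = NULL) {
  stopifnot(inherits(series, "roi_timeseries"))
  if (is.null(fit_start)) {
    if (is.null(series$stim)) stop("no stimulus protocol and no fit_start")
    fit_start <- series$stim$end
  }
  sel <- series$time >= fit_start
  if (sum(sel) < 10) stop("fewer than 10 post-stimulus samples")
  fit_exponential(series$time[sel], series$F[sel], fit_start, offset = TRUE)
}

#' Reacidification rate from an acid-pulse window
#'
#' Fits a single exponential to the trapped-component decay inside the acid
#' window (surface reporter is quenched there, so the remaining signal is
#' from endocytosed, not-yet-reacidified vesicles) and returns the rate
#' `1/tau` in 1/s. A non-decaying window returns a rate near 0 and is
#' flagged.
#'
#' @param series a [roi_timeseries()] (raw fluorescence).
#' @param acid_window `c(start, end)`, s.
#' @return list with `rate` (1/s), `tau` (s), `r2`, `flagged`.
#' @export
fit_reacidification <- function(series, acid_window) {
  stopifnot(inherits(series, "roi_timeseries"), length(acid_window) == 2)
  sel <- series$time >= acid_window[1] & series$time < acid_window[2]
  if (sum(sel) < 6) stop("acid window too short for an exponential fit")
  f <- fit_exponential(series$time[sel], series$F[sel], acid_window[1],
                       offset = TRUE)
  rate <- if (is.finite(f$tau) && f$tau > 0 && !f$flagged) 1 / f$tau else 0
  list(rate = rate, tau = f$tau, r2 = f$r2,
       flagged = f$flagged || rate == 0)
}

#' Peak calcium transient of a dF/F0 series
#'
#' Maximum post-onset value of a dF/F0-normalized series. A peak occurring
#' before the stimulus onset is flagged as an artifact.
#'
#' @param series a [roi_timeseries()] normalized as `dF_over_F0`.
#' @return list with `peak` and `flagged`.
#' @export
peak_transient <- function(series) {
  stopifnot(inherits(series, "roi_timeseries"))
  if (series$normalization != "dF_over_F0")
    stop("peak_transient expects a dF/F0-normalized series")
  onset <- if (!is.null(series$stim)) series$stim$onset else series$time[1]
  if (all(series$F <= 0)) return(list(peak = 0, flagged = FALSE))
  i <- which.max(series$F)
  list(peak = max(series$F[series$time >= onset]),
       flagged = series$time[i] < onset)
}

#' Calcium decay time constant after stimulus end
#'
#' Single-exponential fit with the offset fixed at 0 (calcium returns to the
#' resting level after the train).
#'
#' @param series a dF/F0-normalized [roi_timeseries()].
#' @param post_stim start of the fit, s (default: stimulus end).
#' @return list with `tau` (s), `amplitude`, `r2`, `flagged`.
#' @export
fit_ca_decay <- function(series, post_stim = NULL) {
  stopifnot(inherits(series, "roi_timeseries"))
  if (is.null(post_stim)) {
    if (is.null(series$stim)) stop("no stimulus protocol and no post_stim")
    post_stim <- series$stim$end
  }
  sel <- series$time >= post_stim
  if (sum(sel) < 6) stop("too few post-stimulus samples")
  fit_exponential(series$time[sel], series$F[sel], post_stim, offset = FALSE)
}

#' Fura-2 ratiometric series
#'
#' Elementwise 340/380 nm excitation ratio after per-channel background
#' subtraction; samples with non-positive background-corrected F380 are
#' masked (`NA`). The ratio is invariant to any common positive gain applied
#' to both channels.
#'
#' @param F340,F380 channel intensity series, equal length.
#' @param bg340,bg380 per-channel background levels.
#' @return numeric ratio series.
#' @export
fura_ratio <- function(F340, F380, bg340 = 0, bg380 = 0) {
  stopifnot(length(F340) == length(F380))
  num <- F340 - bg340
  den <- F380 - bg380
  out <- num / den
  out[den <= 0] <- NA_real_
  out
}

#' Photobleaching gate
#'
#' Fits a linear trend to a stimulus-free baseline segment and extrapolates
#' it over the whole recording; the series is rejected if the fractional
#' decline exceeds `max_fraction` (strict inequality, default 2%). Matching
#' the analysis convention, no bleach correction is applied -- the check
#' only gates inclusion.
#'
#' @param series a [roi_timeseries()].
#' @param max_fraction maximum tolerated fractional decline.
#' @param baseline_end end of the stimulus-free segment, s (default:
#'   stimulus onset, or the whole series without a protocol).
#' @return TRUE to keep, FALSE to reject.
#' @export
photobleach_check <- function(series, max_fraction = 0.02,
                              baseline_end = NULL) {
  stopifnot(inherits(series, "roi_timeseries"))
  if (is.null(baseline_end))
    baseline_end <- if (!is.null(series$stim)) series$stim$onset else
      max(series$time)
  sel <- series$time <= baseline_end
  if (sum(sel) < 3) stop("no stimulus-free baseline segment available")
  fit <- stats::lm(F ~ t, data = data.frame(t = series$time[sel],
                                            F = series$F[sel]))
  f_start <- unname(stats::predict(fit,
                                   data.frame(t = min(series$time))))
  f_end <- unname(stats::predict(fit, data.frame(t = max(series$time))))
  decline <- (f_start - f_end) / f_start
  decline <= max_fraction
}
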