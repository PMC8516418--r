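#' Invert the whole-cell equivalent circuit (Lindau-Neher technique)
#'
#' Recovers the three circuit parameters from one complex admittance sample
#' `Y = A + iB` at angular frequency `omega` together with the DC conductance
#' `Gt`, assuming the reversal potential of the DC current is 0 mV. The
#' closed-form solution of the three-element circuit is
#' `Gs = (A^2 + B^2 - A*Gt) / (A - Gt)`,
#' `Gm = Gt*Gs / (Gs - Gt)`,
#' `Cm = B*Gs^2 / (omega * ((Gs - A)^2 + B^2))`.
#'
#' @param Y complex admittance, siemens.
#' @param Gt DC conductance, siemens.
#' @param omega angular frequency, rad/s.
#' @return list with `Cm` (farads), `Gm`, `Gs` (siemens). A purely real
#'   admittance with `Re(Y) == Gt` is the degenerate `Cm = 0` case in which
#'   only `Gt` is identifiable; `Gm = Gt`, `Gs = Inf` is returned (a
#'   consistent factorisation of `Gt`).
#' @export
solve_equivalent_circuit <- function(Y, Gt, omega) {
  stopifnot(length(Y) == 1, Gt >= 0, omega > 0)
  A <- Re(Y); B <- Im(Y)
  tol <- 1e-12 * max(abs(A), Gt, 1e-30)
  if (abs(B) <= tol && abs(A - Gt) <= tol)
    return(list(Cm = 0, Gm = Gt, Gs = Inf))
  if (A <= Gt)
    stop("non-physical input: Re(Y) must exceed Gt for a three-element circuit")
  if (B < 0)
    stop("non-physical input: Im(Y) < 0")
  Gs <- (A^2 + B^2 - A * Gt) / (A - Gt)
  Gm <- Gt * Gs / (Gs - Gt)
  Cm <- B * Gs^2 / (omega * ((Gs - A)^2 + B^2))
  if (Gs <= 0 || Gm < 0)
    stop("non-physical input: recovered conductances are not positive")
  list(Cm = Cm, Gm = Gm, Gs = Gs)
}

#' Whole-cell capacitance record container
#'
#' @param time seconds. @param Cm membrane capacitance series, farads.
#' @param leak leak conductance, siemens.
#' @param depol_times data.frame with columns `onset`, `end` (s) for each
#'   depolarization, or NULL.
#' @param Gm,Gs optional conductance series, siemens.
#' @export
whole_cell_record <- function(time, Cm, leak = 0, depol_times = NULL,
                              Gm = NULL, Gs = NULL) {
  stopifnot(length(time) == length(Cm))
  structure(list(time = time, Cm = Cm, leak = leak,
                 depol_times = depol_times, Gm = Gm, Gs = Gs),
            class = "whole_cell_record")
}

#' Exocytic capacitance jump after a depolarization
#'
#' `delta Cm` is the mean Cm over the 40-100 ms interval after the end of the
#' depolarization minus the baseline, itself the mean over the 50 ms segment
#' preceding the depolarization onset. The first 40 ms after the pulse are
#' skipped because the transient gating-capacitance artifact has decayed by
#' then.
#'
#' @param record a [whole_cell_record()].
#' @param depol_onset,depol_end depolarization onset and end, s.
#' @param post_window interval after `depol_end` averaged for the response, s.
#' @param baseline_len pre-depolarization baseline length, s.
#' @return delta Cm in farads.
#' @export
delta_cm_exocytosis <- function(record, depol_onset, depol_end,
                                post_window = c(0.040, 0.100),
                                baseline_len = 0.050) {
  stopifnot(inherits(record, "whole_cell_record"), depol_end > depol_onset)
  tt <- record$time
  post <- tt >= depol_end + post_window[1] & tt <= depol_end + post_window[2]
  pre <- tt >= depol_onset - baseline_len & tt < depol_onset
  if (sum(post) < 2 || sum(pre) < 2)
    stop("insufficient samples in the baseline or response window")
  mean(record$Cm[post]) - mean(record$Cm[pre])
}

#' Leak-conductance quality control
#'
#' Cells with a leak conductance strictly greater than `max_leak` (default
#' 150 pS) are discarded.
#'
#' @param record a [whole_cell_record()] (or anything with a `leak` field).
#' @param max_leak maximum accepted leak, siemens.
#' @return TRUE to keep, FALSE to discard.
#' @export
qc_leak <- function(record, max_leak = 150e-12) {
  record$leak <= max_leak
}

#' Calcium-influx charge from an evoked inward current
#'
#' Integrates the absolute baseline-subtracted current over the
#' depolarization, excluding the first `exclude` seconds (default 10 ms,
#' which removes the unblocked Na+ transient). With the current in pA and
#' time in seconds the returned charge is in pC.
#'
#' @param time sample times, s. @param I current, pA.
#' @param depol_onset,depol_end depolarization window, s.
#' @param exclude initial exclusion, s.
#' @param baseline_len pre-depolarization segment used for the baseline, s.
#' @return charge in pC.
#' @export
ca_influx_charge <- function(time, I, depol_onset, depol_end,
                             exclude = 0.010, baseline_len = 0.050) {
  stopifnot(depol_end > depol_onset)
  if (exclude >= depol_end - depol_onset)
    stop("exclusion window covers the whole depolarization")
  pre <- time >= depol_onset - baseline_len & time < depol_onset
  base <- if (any(pre)) mean(I[pre]) else 0
  idx <- time >= depol_onset + exclude & time <= depol_end
  if (sum(idx) < 2) stop("depolarization window not inside the trace")
  trapz(time[idx], abs(I[idx] - base))
}
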