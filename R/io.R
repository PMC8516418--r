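#' Write and read traces as CSV with a JSON metadata sidecar
#'
#' Traces are stored as plain CSV (one time column plus the channel
#' columns); acquisition metadata (sampling rate, lock-in frequency, units)
#' and any ground truth go to `<path>.json`. The round trip is lossless to
#' full double precision (values are written with 17 significant digits).
#'
#' @param trace a `lockin_trace`, `patch_current_trace`, or
#'   `amperometric_trace`.
#' @param path CSV file path.
#' @param truth optional `ground_truth` object stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, truth = NULL) {
  if (inherits(trace, "lockin_trace")) {
    df <- data.frame(time_s = trace$time, Re_S = trace$Re, Im_S = trace$Im)
    meta <- list(class = "lockin_trace",
                 sampling_rate = trace$sampling_rate,
                 lockin_frequency = trace$lockin_frequency,
                 units = list(time = "s", Re = "S", Im = "S"))
  } else if (inherits(trace, "patch_current_trace")) {
    df <- data.frame(time_s = trace$time, I_pA = trace$I)
    meta <- list(class = "patch_current_trace",
                 sampling_rate = trace$sampling_rate,
                 V_patch_mV = trace$V_patch, filter_hz = trace$filter_hz,
                 t_event = trace$t_event,
                 units = list(time = "s", I = "pA"))
  } else if (inherits(trace, "amperometric_trace")) {
    df <- data.frame(time_s = trace$time, I_pA = trace$I)
    meta <- list(class = "amperometric_trace",
                 sampling_rate = trace$sampling_rate,
                 stim_time = trace$stim_time,
                 units = list(time = "s", I = "pA"))
  } else stop("unsupported trace class")
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth)) meta$truth <- serialize_truth(truth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @return `read_trace_csv`: the reconstructed trace object, with any
#'   ground truth attached as the `truth` attribute.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  out <- switch(meta$class,
    lockin_trace = lockin_trace(df$time_s, df$Re_S, df$Im_S,
                                meta$sampling_rate, meta$lockin_frequency),
    patch_current_trace = patch_current_trace(
      df$time_s, df$I_pA, meta$V_patch_mV, meta$sampling_rate,
      meta$filter_hz,
      if (is.null(meta$t_event)) NA_real_ else meta$t_event),
    amperometric_trace = amperometric_trace(df$time_s, df$I_pA,
                                            meta$sampling_rate,
                                            meta$stim_time),
    stop("unknown trace class in sidecar: ", meta$class))
  if (!is.null(meta$truth)) attr(out, "truth") <- meta$truth
  out
}

# Ground truth to a JSON-ready list (drops closures, keeps sampled profiles).
serialize_truth <- function(truth) {
  x <- unclass(truth)
  x$cfg <- NULL
  x
}

#' Write a per-event capacitance table as CSV
#'
#' Columns follow the reporting convention: capacitance in fF, durations in
#' ms, conductances in pS.
#'
#' @param events a `capacitance_events` table.
#' @param path CSV path. @param cell_id identifier column value.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path, cell_id = "cell1") {
  df <- data.frame(cell_id = cell_id,
                   t_step_s = events$t_step,
                   direction = events$direction,
                   Cv_fF = events$Cv * 1e15,
                   duration_ms = events$fission_pore_duration * 1e3,
                   Gp_mean_pS = events$Gp_mean * 1e12,
                   kinetics_valid = events$kinetics_valid)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' Requires the `tiff` package. Frame times default to a uniform grid at
#' `frame_rate`.
#'
#' @param path TIFF file. @param frame_rate frames per second.
#' @return an `image_stack`.
#' @export
read_image_stack <- function(path, frame_rate = 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF stacks requires the 'tiff' package")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                             length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  structure(list(frames = frames,
                 frame_times = (seq_along(pages) - 1) / frame_rate),
            class = "image_stack")
}
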