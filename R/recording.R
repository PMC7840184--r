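#' Calibrated multi-channel time-lapse recording
#'
#' The central container of the pipeline: one or more co-registered channels
#' (each an H x W x T array of non-negative intensities in arbitrary units)
#' together with the acquisition calibration. Channel names are drawn from
#' the controlled vocabulary `f340`, `f380`, `gcamp`, `brightfield`,
#' `background`.
#'
#' @param channels named list of H x W x T numeric arrays; all channels must
#'   share identical dimensions
#' @param dt frame interval in seconds (> 0)
#' @param pixel_size microns per pixel (> 0)
#' @param t0_index 1-based reference frame index used for registration and
#'   ROI definition (defaults to the first frame)
#' @return an object of class `TimeLapseRecording` with accessors
#'   [n_frames()], [frame_times()], [get_channel()]
#' @examples
#' arr <- array(runif(4 * 4 * 3), c(4, 4, 3))
#' rec <- TimeLapseRecording(list(brightfield = arr), dt = 1, pixel_size = 2)
#' n_frames(rec)
#' @export
TimeLapseRecording <- function(channels, dt, pixel_size, t0_index = 1L) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)) ||
      any(names(channels) == "")) {
    stop("`channels` must be a non-empty named list of arrays")
  }
  known <- c("f340", "f380", "gcamp", "brightfield", "background")
  unknown <- setdiff(names(channels), known)
  if (length(unknown)) {
    warning("non-standard channel label(s): ", paste(unknown, collapse = ", "))
  }
  dims <- lapply(channels, dim)
  for (d in dims) {
    if (is.null(d) || length(d) != 3L) stop("every channel must be an H x W x T array")
  }
  ref <- dims[[1]]
  for (d in dims) if (!all(d == ref)) stop("all channels must share identical T, H, W")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a positive scalar (seconds)")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || !is.finite(pixel_size) ||
      pixel_size <= 0) {
    stop("`pixel_size` must be a positive scalar (microns/pixel)")
  }
  t0_index <- as.integer(t0_index)
  if (t0_index < 1L || t0_index > ref[3]) stop("`t0_index` out of range")
  structure(
    list(channels = channels, dt = dt, pixel_size = pixel_size, t0_index = t0_index),
    class = "TimeLapseRecording"
  )
}

#' @rdname TimeLapseRecording
#' @param rec a `TimeLapseRecording`
#' @export
n_frames <- function(rec) dim(rec$channels[[1]])[3]

#' @rdname TimeLapseRecording
#' @export
frame_times <- function(rec) (seq_len(n_frames(rec)) - 1) * rec$dt

#' @rdname TimeLapseRecording
#' @param name channel label
#' @export
get_channel <- function(rec, name) {
  if (!name %in% names(rec$channels)) {
    stop("channel '", name, "' not present (have: ",
         paste(names(rec$channels), collapse = ", "), ")")
  }
  rec$channels[[name]]
}

#' @export
print.TimeLapseRecording <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "TimeLapseRecording: %d x %d px, %d frames, dt = %g s, %g um/px\n  channels: %s\n",
    d[1], d[2], d[3], x$dt, x$pixel_size, paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}

#' Stimulus protocol
#'
#' Onset times are seconds on the recording clock (t = 0 at the first frame).
#'
#' @param onsets strictly increasing vector of stimulus onset times (s)
#' @param duration stimulus duration (s, > 0)
#' @param agent free-text agent name (e.g. "ATP")
#' @param concentration agent concentration in micromolar (>= 0)
#' @export
StimulusProtocol <- function(onsets, duration, agent = "ATP", concentration = 100) {
  onsets <- as.numeric(onsets)
  if (length(onsets) == 0L || any(!is.finite(onsets)) || is.unsorted(onsets, strictly = TRUE)) {
    stop("`onsets` must be a non-empty strictly increasing numeric vector")
  }
  if (duration <= 0) stop("`duration` must be > 0")
  if (concentration < 0) stop("`concentration` must be >= 0")
  structure(
    list(onsets = onsets, duration = duration, agent = agent,
         concentration = concentration),
    class = "StimulusProtocol"
  )
}

#' Time-stamped signal trace for one ROI
#'
#' @param times strictly increasing sample times (s)
#' @param values fluorescence ratio (f340/f380), normalized intensity change,
#'   or raw ROI mean, matching `kind`
#' @param kind one of "ratio", "dff", "raw"
#' @param roi optional ROI label carried into outputs
#' @param meta optional named list of provenance (e.g. the dF/F convention)
#' @export
SignalTrace <- function(times, values, kind = c("ratio", "dff", "raw"),
                        roi = NA_character_, meta = list()) {
  kind <- match.arg(kind)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values must have equal length")
  if (length(times) && is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  if (kind == "ratio" && any(values <= 0, na.rm = TRUE)) {
    stop("ratio traces must be strictly positive")
  }
  structure(list(times = times, values = values, kind = kind, roi = roi, meta = meta),
            class = "SignalTrace")
}

#' Dense per-frame displacement field
#'
#' `dx`/`dy` hold, per frame i and pixel (r, c), the vector v such that the
#' reference image at (r, c) matches frame i at (r + dy, c + dx): in
#' `to_t0` mode the reference is the t0 frame, in `consecutive` mode the
#' previous frame. Warping frame i by the field (see [apply_displacement()])
#' returns it to reference geometry.
#'
#' @param dx,dy H x W x T numeric arrays of displacement components (pixels)
#' @param reference_mode "to_t0" or "consecutive"
#' @param border_margin pixels near the border flagged as unreliable and
#'   excluded from ROI statistics
#' @export
DisplacementField <- function(dx, dy, reference_mode = c("to_t0", "consecutive"),
                              border_margin = 0L) {
  reference_mode <- match.arg(reference_mode)
  if (!identical(dim(dx), dim(dy)) || length(dim(dx)) != 3L) {
    stop("dx and dy must be H x W x T arrays of identical dimension")
  }
  if (any(!is.finite(dx)) || any(!is.finite(dy))) stop("displacement vectors must be finite")
  structure(
    list(dx = dx, dy = dy, reference_mode = reference_mode,
         border_margin = as.integer(border_margin)),
    class = "DisplacementField"
  )
}

#' Per-frame contraction metrics derived from a displacement field
#'
#' @param s flow strength per frame (ROI-mean displacement norm, pixels, >= 0)
#' @param smoothing_window odd moving-average window (frames) applied to `s`
#'   before differencing
#' @param dt frame interval (s)
#' @return `FlowSeries` with elements `s`, `s_smooth`, `c`
#'   (c[i] = s_smooth[i+1] - s_smooth[i], length length(s) - 1), and times.
#' @export
FlowSeries <- function(s, smoothing_window = 5L, dt = 1) {
  s <- as.numeric(s)
  if (any(!is.finite(s)) || any(s < 0)) stop("flow strength must be finite and >= 0")
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 1L || smoothing_window %% 2L == 0L) {
    stop("`smoothing_window` must be an odd integer >= 1")
  }
  if (smoothing_window > length(s)) stop("`smoothing_window` exceeds series length")
  s_smooth <- moving_average(s, smoothing_window)
  structure(
    list(s = s, s_smooth = s_smooth, c = diff(s_smooth),
         smoothing_window = smoothing_window, dt = dt,
         times = (seq_along(s) - 1) * dt),
    class = "FlowSeries"
  )
}
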