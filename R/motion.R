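# Contraction metrics computed from displacement fields.

#' Flow strength s_i within an ROI
#'
#' s_i is the mean Euclidean norm of the displacement vectors over the ROI
#' pixels at frame i — the contraction-magnitude metric. Pixels within the
#' field's border margin (where dense flow is ill-posed) are excluded.
#'
#' @param field [DisplacementField]
#' @param roi [Roi], logical mask, or NULL for the whole frame
#' @return numeric vector, one value (px) per frame
#' @export
flow_strength <- function(field, roi = NULL) {
  d <- dim(field$dx)
  H <- d[1]; W <- d[2]
  mask <- if (is.null(roi)) matrix(TRUE, H, W)
          else if (inherits(roi, "Roi")) roi$mask
          else roi
  if (!identical(dim(mask), c(H, W))) stop("ROI mask does not match field dims")
  m <- field$border_margin
  if (m > 0 && m < min(H, W) / 2) {
    border <- matrix(TRUE, H, W)
    border[(m + 1):(H - m), (m + 1):(W - m)] <- FALSE
    mask <- mask & !border
  }
  if (!any(mask)) stop("ROI empty after border exclusion")
  vapply(seq_len(d[3]), function(i) {
    mean(sqrt(field$dx[, , i][mask]^2 + field$dy[, , i][mask]^2))
  }, numeric(1))
}

#' Flow change c_i from a flow-strength series
#'
#' The s series is smoothed with a centered moving-average filter (shrinking
#' windows at the edges; window 1 = no smoothing, bitwise), then differenced:
#' c_i = s_smooth_i - s_smooth_{i-1}. With window 1 the c series telescopes
#' exactly: sum(c) = s_k - s_0.
#'
#' @param s flow-strength vector (length >= 2)
#' @param smoothing_window odd moving-average window (frames)
#' @param dt frame interval (s)
#' @return [FlowSeries]
#' @export
flow_change <- function(s, smoothing_window = 5L, dt = 1) {
  if (length(s) < 2L) stop("need at least 2 samples")
  FlowSeries(s, smoothing_window = smoothing_window, dt = dt)
}

#' Area under a series over a post-onset window
#'
#' Trapezoidal integral over [onset, onset + window]; the companion basal
#' AUC integrates the equal-length pre-onset window [onset - window, onset]
#' when the recording covers it. Values at the exact window edges are
#' obtained by linear interpolation. A window extending past the end of the
#' recording is truncated and flagged.
#'
#' @param series numeric values
#' @param times sample times (s), equal length
#' @param onset_s window start (s)
#' @param window_s window length (s); the whole-mount transport analysis
#'   used 60 s after stimulation onset
#' @param rectify integrate |series| instead of the signed series
#' @return list with `auc`, `auc_basal` (NA when the pre-window is not
#'   covered), `truncated` flag and `window_s`
#' @export
auc_window <- function(series, times, onset_s, window_s = 60, rectify = FALSE) {
  if (window_s <= 0) stop("window_s must be > 0")
  if (length(series) != length(times)) stop("series/times length mismatch")
  if (onset_s < times[1] || onset_s > times[length(times)]) {
    stop("onset outside the recording")
  }
  y <- if (rectify) abs(series) else series
  seg_int <- function(a, b) {
    if (b <= a) return(NA_real_)
    inner <- times > a & times < b
    xs <- c(a, times[inner], b)
    ys <- c(interp_at(times, y, a), y[inner], interp_at(times, y, b))
    trapz(xs, ys)
  }
  t_end <- min(onset_s + window_s, times[length(times)])
  truncated <- (onset_s + window_s) > times[length(times)]
  if (truncated) warning("AUC window truncated at recording end")
  a_post <- seg_int(onset_s, t_end)
  a_basal <- if (onset_s - window_s >= times[1]) {
    seg_int(onset_s - window_s, onset_s)
  } else NA_real_
  list(auc = a_post, auc_basal = a_basal, truncated = truncated,
       window_s = window_s)
}

#' Windowed-MSE motion measure
#'
#' For each consecutive frame pair and each pixel, finds the integer shift d
#' with max-norm at most `max_distance` minimizing the Gaussian-weighted
#' local mean squared error between the current frame around the pixel and
#' the previous frame around the shifted position. Ties are broken toward
#' the smallest Euclidean norm, then lexicographically (dy, then dx), so a
#' static stack yields exactly zero motion. Defaults follow the in-vivo
#' analysis settings (sigma = 1, max distance = 3).
#'
#' @param stack H x W x T array (stabilized/preprocessed)
#' @param sigma Gaussian weighting sigma (px)
#' @param max_distance maximum shift component (px, integer)
#' @param roi optional [Roi] or mask for the summary series
#' @return list with `series` (ROI-mean motion per frame pair, length T-1)
#'   and `maps` (H x W x (T-1) array of per-pixel displacement norms)
#' @export
windowed_mse_motion <- function(stack, sigma = 1, max_distance = 3L, roi = NULL) {
  d <- dim(stack)
  if (length(d) != 3L || d[3] < 2L) stop("need an H x W x T stack with T >= 2")
  H <- d[1]; W <- d[2]; Tn <- d[3]
  max_distance <- as.integer(max_distance)
  if (sigma <= 0) stop("sigma must be > 0")
  if (max_distance < 1L) stop("max_distance must be >= 1")
  if (max_distance >= min(H, W) / 2) stop("max_distance too large for image")
  mask <- if (is.null(roi)) matrix(TRUE, H, W)
          else if (inherits(roi, "Roi")) roi$mask else roi

  shifts <- expand.grid(dy = (-max_distance):max_distance,
                        dx = (-max_distance):max_distance)
  nrm <- sqrt(shifts$dx^2 + shifts$dy^2)
  ord <- order(nrm, shifts$dy, shifts$dx)
  shifts <- shifts[ord, ]; nrm <- nrm[ord]

  k <- gauss_kernel1d(sigma)
  maps <- array(0, c(H, W, Tn - 1L))
  series <- numeric(Tn - 1L)
  for (i in 2:Tn) {
    prev <- stack[, , i - 1L]; cur <- stack[, , i]
    best <- matrix(Inf, H, W)
    bestn <- matrix(0, H, W)
    for (s in seq_len(nrow(shifts))) {
      dyx <- shifts$dy[s]; dxx <- shifts$dx[s]
      diff2 <- (cur - shift_int(prev, dyx, dxx))^2
      mse <- conv1_replicate(conv1_replicate(diff2, k, 1L), k, 2L)
      upd <- mse < best   # strict: earlier (smaller-norm) shifts win ties
      best[upd] <- mse[upd]
      bestn[upd] <- nrm[s]
    }
    maps[, , i - 1L] <- bestn
    series[i - 1L] <- mean(bestn[mask])
  }
  list(series = series, maps = maps)
}

#' Detect contraction events in a motion series
#'
#' Events are maximal runs where the series exceeds a robust baseline
#' (median + k_sd * 1.4826 * MAD) for at least `min_frames` samples; runs
#' separated by a gap shorter than 2 frames are merged.
#'
#' @param series motion values (e.g. flow change or flow strength)
#' @param times sample times (s)
#' @param k_sd threshold in robust-SD units above the median
#' @param min_frames minimum above-threshold run length
#' @return data.frame(onset_s, duration_s, peak); zero rows when quiet
#' @export
detect_contractions <- function(series, times, k_sd = 3, min_frames = 2L) {
  if (length(series) < 10L) stop("need >= 10 samples for baseline estimation")
  med <- stats::median(series)
  sd_rob <- stats::mad(series)
  if (sd_rob == 0) sd_rob <- max(1e-12, 0.05 * max(abs(series - med)))
  thr <- med + k_sd * sd_rob
  above <- series > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(ev) > 1L) {
    keep <- ev[1, , drop = FALSE]
    for (j in 2:nrow(ev)) {
      if (ev$start[j] - keep$end[nrow(keep)] - 1L < 2L) {   # gap < 2 frames
        keep$end[nrow(keep)] <- ev$end[j]
      } else keep <- rbind(keep, ev[j, ])
    }
    ev <- keep
  }
  if (nrow(ev)) ev <- ev[(ev$end - ev$start + 1L) >= min_frames, , drop = FALSE]
  if (!nrow(ev)) {
    return(data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      peak = numeric(0)))
  }
  dt <- if (length(times) > 1L) times[2] - times[1] else 1
  data.frame(
    onset_s = times[ev$start],
    duration_s = (ev$end - ev$start + 1L) * dt,
    peak = vapply(seq_len(nrow(ev)),
                  function(j) max(series[ev$start[j]:ev$end[j]]), numeric(1))
  )
}

#' Full per-ROI motion quantification
#'
#' Convenience wrapper: flow strength within the ROI, smoothed flow change,
#' and post-stimulus vs basal AUC of the (by default rectified) flow-change
#' series over the standard 60 s window.
#'
#' @param field [DisplacementField]
#' @param roi [Roi] or mask
#' @param times frame times (s)
#' @param onset_s stimulation onset (s)
#' @param window_s AUC window (s)
#' @param smoothing_window moving-average window for the s series
#' @param rectify integrate |c| (default) instead of signed c
#' @return list of class `MotionResult`: `flow` ([FlowSeries]), `auc_post`,
#'   `auc_basal`, `window_s`
#' @export
quantify_motion <- function(field, roi, times, onset_s, window_s = 60,
                            smoothing_window = 5L, rectify = TRUE) {
  s <- flow_strength(field, roi)
  fs <- flow_change(s, smoothing_window = smoothing_window,
                    dt = if (length(times) > 1) times[2] - times[1] else 1)
  a <- auc_window(fs$c, times[-1], onset_s, window_s, rectify = rectify)
  structure(list(flow = fs, auc_post = a$auc, auc_basal = a$auc_basal,
                 window_s = window_s, rectified = rectify),
            class = "MotionResult")
}
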