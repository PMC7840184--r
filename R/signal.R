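# Per-ROI calcium trace extraction from stabilized stacks.

#' Baseline specification
#'
#' @param window c(start_s, end_s); must end at or before the first
#'   stimulus onset
#' @param statistic "mean" or "median"
#' @export
baseline_spec <- function(window, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (length(window) != 2L || window[2] <= window[1]) {
    stop("baseline window must be c(start, end) with end > start")
  }
  structure(list(window = window, statistic = statistic), class = "BaselineSpec")
}

#' Fura-2 ratio trace: mean of per-pixel f340/f380 ratios
#'
#' Per frame, the value is the mean over ROI pixels of the pixelwise
#' f340/f380 ratio (mean of ratios, not ratio of means). Pixels whose f380
#' falls below `floor_frac` of the channel maximum are excluded from the
#' mean (and counted), preventing ratio blow-up in dark pixels.
#'
#' @param f340,f380 stabilized H x W x T arrays
#' @param roi [Roi] or logical mask
#' @param dt frame interval (s)
#' @param floor_frac f380 exclusion floor as a fraction of the channel max
#' @param method "mean_of_ratios" (the defining formula) or "ratio_of_means"
#'   (sensitivity alternative)
#' @return [SignalTrace] of kind "ratio"; `meta$n_excluded` counts excluded
#'   pixel-frames
#' @export
extract_ratio_trace <- function(f340, f380, roi, dt = 1, floor_frac = 0.01,
                                method = c("mean_of_ratios", "ratio_of_means")) {
  method <- match.arg(method)
  if (!identical(dim(f340), dim(f380))) stop("f340/f380 shape mismatch")
  mask <- if (inherits(roi, "Roi")) roi$mask else roi
  if (!identical(dim(mask), dim(f340)[1:2])) stop("ROI does not match stack dims")
  Tn <- dim(f340)[3]
  eps <- floor_frac * max(f380)
  vals <- numeric(Tn)
  n_excl <- 0L
  for (i in seq_len(Tn)) {
    a <- f340[, , i][mask]; b <- f380[, , i][mask]
    ok <- b > eps
    n_excl <- n_excl + sum(!ok)
    if (!any(ok)) stop("all ROI pixels excluded at frame ", i, " (f380 below floor)")
    vals[i] <- if (method == "mean_of_ratios") mean(a[ok] / b[ok])
               else mean(a[ok]) / mean(b[ok])
  }
  SignalTrace((seq_len(Tn) - 1) * dt, vals, kind = "ratio",
              roi = if (inherits(roi, "Roi")) roi$label else NA_character_,
              meta = list(method = method, n_excluded = n_excl))
}

#' Normalized intensity-change (dF/F) trace
#'
#' F_i is the ROI-mean intensity at frame i and F_baseline the baseline
#' statistic over the pre-stimulus window. Two denominator conventions are
#' supported: the conventional dF/F0 = (F_i - F_b)/F_b (default, "dff0")
#' and the current-frame-denominator form (F_i - F_b)/F_i ("dffi"); the one
#' used is recorded in the trace metadata.
#'
#' @param stack stabilized H x W x T array
#' @param roi [Roi] or mask
#' @param baseline [baseline_spec()]; the window must lie within the
#'   recording and contain >= 3 samples
#' @param dt frame interval (s)
#' @param convention "dff0" or "dffi"
#' @return [SignalTrace] of kind "dff"
#' @export
extract_dff_trace <- function(stack, roi, baseline, dt = 1,
                              convention = c("dff0", "dffi")) {
  convention <- match.arg(convention)
  mask <- if (inherits(roi, "Roi")) roi$mask else roi
  Tn <- dim(stack)[3]
  times <- (seq_len(Tn) - 1) * dt
  Fi <- vapply(seq_len(Tn), function(i) mean(stack[, , i][mask]), numeric(1))
  in_win <- times >= baseline$window[1] & times <= baseline$window[2]
  if (sum(in_win) < 3L) stop("baseline window must contain >= 3 samples")
  Fb <- if (baseline$statistic == "mean") mean(Fi[in_win]) else stats::median(Fi[in_win])
  if (Fb <= 0) stop("non-positive baseline")
  vals <- if (convention == "dff0") (Fi - Fb) / Fb else (Fi - Fb) / Fi
  SignalTrace(times, vals, kind = "dff",
              roi = if (inherits(roi, "Roi")) roi$label else NA_character_,
              meta = list(convention = convention, f_baseline = Fb))
}

#' Remove a linear baseline drift from a trace
#'
#' A least-squares line is fitted to the samples outside the protected
#' (stimulus/response) windows and subtracted; the mean of the unprotected
#' samples is preserved, so protected transients keep their amplitude
#' relative to the corrected baseline.
#'
#' @param trace [SignalTrace]
#' @param protected_windows list of c(start_s, end_s) intervals excluded
#'   from the fit
#' @return detrended [SignalTrace]
#' @export
detrend_linear <- function(trace, protected_windows = list()) {
  t <- trace$times; v <- trace$values
  free <- rep(TRUE, length(t))
  for (w in protected_windows) free <- free & !(t >= w[1] & t <= w[2])
  if (sum(free) < 2L) stop("fewer than 2 samples outside protected windows")
  fit <- stats::lm.fit(cbind(1, t[free]), v[free])
  line <- fit$coefficients[1] + fit$coefficients[2] * t
  out <- v - line + mean(v[free])
  SignalTrace(t, out, kind = if (trace$kind == "ratio") "raw" else trace$kind,
              roi = trace$roi, meta = c(trace$meta, list(detrended = TRUE)))
}

#' Classify a trace as responder / non-responder
#'
#' Responder iff the trace exceeds baseline mean + k_sd * baseline SD for at
#' least `min_frames` consecutive samples inside the response window after
#' stimulus onset. With a degenerate (zero-SD) baseline an absolute floor of
#' 1% of the baseline mean (or 1e-6) is used.
#'
#' @param trace [SignalTrace]
#' @param protocol [StimulusProtocol]
#' @param baseline [baseline_spec()]
#' @param k_sd threshold in baseline-SD units
#' @param min_frames minimum consecutive supra-threshold samples
#' @param response_window_s post-onset search window (s)
#' @return list with `responder` (logical), `amplitude` (peak - baseline
#'   mean within the window; 0 for non-responders), `threshold`
#' @export
classify_responder <- function(trace, protocol, baseline, k_sd = 3,
                               min_frames = 2L, response_window_s = 60) {
  t <- trace$times; v <- trace$values
  in_base <- t >= baseline$window[1] & t <= baseline$window[2]
  if (sum(in_base) < 3L) stop("baseline window must contain >= 3 samples")
  mu <- mean(v[in_base]); sd_b <- stats::sd(v[in_base])
  if (!is.finite(sd_b) || sd_b == 0) sd_b <- max(abs(mu) * 0.01, 1e-6)
  thr <- mu + k_sd * sd_b
  onset <- protocol$onsets[1]
  in_resp <- t >= onset & t <= onset + response_window_s
  above <- v > thr & in_resp
  r <- rle(above)
  hit <- any(r$values & r$lengths >= min_frames)
  amp <- if (any(in_resp)) max(v[in_resp]) - mu else 0
  list(responder = hit, amplitude = if (hit) amp else 0, threshold = thr)
}
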