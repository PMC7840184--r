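# Tubule straightening, kymograph construction and wave-velocity fitting.

#' Straighten a tubule along a polyline
#'
#' The polyline is spline-smoothed (cubic, parametrized by arc length),
#' resampled at 1 px steps, and the stack is resampled bilinearly along the
#' normals, giving a T-frame stack of size width_px x L (arc length along
#' the output columns, so arc length is preserved). Columns where the local
#' curvature radius falls below width/2 (self-intersecting normals) are
#' flagged in the `flagged_columns` attribute.
#'
#' @param stack H x W x T array
#' @param polyline n x 2 matrix of (x, y) vertices, 0-based pixel coords
#' @param width_px transverse sampling width (px, >= 3)
#' @return width_px x L x T array with attributes `arc_px` (column arc
#'   positions) and `flagged_columns`
#' @export
straighten_tubule <- function(stack, polyline, width_px = 11L) {
  polyline <- as.matrix(polyline)
  if (width_px < 3L) stop("width_px must be >= 3")
  d <- dim(stack)
  H <- d[1]; W <- d[2]; Tn <- d[3]
  if (any(polyline[, 1] < 0 | polyline[, 1] > W - 1 |
          polyline[, 2] < 0 | polyline[, 2] > H - 1)) {
    stop("polyline outside image")
  }
  # chord-length parametrization + cubic spline through the vertices
  seg <- sqrt(rowSums(diff(polyline)^2))
  if (any(seg == 0)) stop("repeated polyline vertices")
  s0 <- c(0, cumsum(seg))
  total <- s0[length(s0)]
  n_out <- max(2L, as.integer(round(total)) + 1L)
  ss <- seq(0, total, length.out = n_out)
  fx <- if (nrow(polyline) > 2L) stats::splinefun(s0, polyline[, 1], method = "natural")
        else stats::approxfun(s0, polyline[, 1])
  fy <- if (nrow(polyline) > 2L) stats::splinefun(s0, polyline[, 2], method = "natural")
        else stats::approxfun(s0, polyline[, 2])
  cx <- fx(ss); cy <- fy(ss)
  # tangents / curvature by central differences on the resampled curve
  tx <- c(cx[2] - cx[1], (cx[-(1:2)] - cx[1:(n_out - 2)]) / 2, cx[n_out] - cx[n_out - 1])
  ty <- c(cy[2] - cy[1], (cy[-(1:2)] - cy[1:(n_out - 2)]) / 2, cy[n_out] - cy[n_out - 1])
  tn <- sqrt(tx^2 + ty^2); tx <- tx / tn; ty <- ty / tn
  nxv <- -ty; nyv <- tx
  dtx <- c(0, diff(tx)); dty <- c(0, diff(ty))
  curvature <- sqrt(dtx^2 + dty^2)            # |dT/ds| at ~1 px steps
  flagged <- which(curvature > 2 / width_px)  # radius < width/2

  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = width_px)
  # sample coordinates (1-based for bilinear_sample)
  X <- outer(offs, nxv) + matrix(cx + 1, width_px, n_out, byrow = TRUE)
  Y <- outer(offs, nyv) + matrix(cy + 1, width_px, n_out, byrow = TRUE)
  out <- array(0, c(width_px, n_out, Tn))
  for (t in seq_len(Tn)) {
    out[, , t] <- matrix(bilinear_sample(stack[, , t], as.vector(X), as.vector(Y)),
                         width_px, n_out)
  }
  attr(out, "arc_px") <- ss
  attr(out, "flagged_columns") <- flagged
  out
}

#' Build a kymograph from a straightened motion stack
#'
#' Each frame's columns (transversal line profiles perpendicular to the
#' straightened axis) are averaged across the transverse direction, then
#' pooled into arc-length bins: the result is a space x time matrix of mean
#' motion intensity.
#'
#' @param straight width x L x T array from [straighten_tubule()] applied
#'   to motion maps (e.g. [windowed_mse_motion()] maps or flow norms)
#' @param bin_um spatial bin size (um)
#' @param pixel_size microns per pixel
#' @param dt frame interval (s)
#' @return object of class `Kymograph`: `matrix` (bins x T),
#'   `bin_centers_um`, `bin_um`, `dt`
#' @export
build_kymograph <- function(straight, bin_um = 10, pixel_size = 1, dt = 1) {
  if (bin_um < pixel_size) stop("bin smaller than pixel size")
  d <- dim(straight)
  L <- d[2]; Tn <- d[3]
  arc_px <- attr(straight, "arc_px")
  if (is.null(arc_px)) arc_px <- seq_len(L) - 1
  arc_um <- arc_px * pixel_size
  bin <- floor(arc_um / bin_um)
  bins <- sort(unique(bin))
  mat <- matrix(0, length(bins), Tn)
  for (t in seq_len(Tn)) {
    colmean <- colMeans(straight[, , t, drop = FALSE][, , 1, drop = FALSE][, , 1])
    mat[, t] <- as.vector(tapply(colmean, factor(bin, levels = bins), mean))
  }
  structure(list(matrix = mat,
                 bin_centers_um = (bins + 0.5) * bin_um,
                 bin_um = bin_um, dt = dt),
            class = "Kymograph")
}

#' Estimate wave propagation velocity from a kymograph
#'
#' Per spatial bin, the onset is the first time its trace crosses
#' `threshold_frac` of its own maximum (linear interpolation between
#' samples); velocity is the slope of the least-squares regression of
#' position (um) on onset time (s), so the sign gives the propagation
#' direction. The fit is invalid when fewer than 5 bins cross, when the
#' onset spread is below 2 frames (synchronous contraction has no defined
#' velocity), or when r^2 < 0.5.
#'
#' @param kymo [build_kymograph()] output
#' @param threshold_frac onset threshold as a fraction of each bin's max
#' @return object of class `WaveFit`: `velocity_um_s`, `r_squared`,
#'   `onsets` (data.frame position_um, onset_s), `valid`, `reason`
#' @export
estimate_wave_velocity <- function(kymo, threshold_frac = 0.5) {
  mat <- kymo$matrix
  nb <- nrow(mat); Tn <- ncol(mat)
  times <- (seq_len(Tn) - 1) * kymo$dt
  onsets <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    tr <- mat[b, ]
    mx <- max(tr)
    if (mx <= 0) next
    thr <- threshold_frac * mx
    above <- which(tr >= thr)
    if (!length(above)) next
    j <- above[1]
    onsets[b] <- if (j == 1L) times[1] else {
      # linear interpolation between the straddling samples
      times[j - 1L] + (thr - tr[j - 1L]) / (tr[j] - tr[j - 1L]) * kymo$dt
    }
  }
  ok <- !is.na(onsets)
  mkfit <- function(valid, reason, v = NA_real_, r2 = NA_real_) {
    structure(list(velocity_um_s = v, r_squared = r2,
                   onsets = data.frame(position_um = kymo$bin_centers_um[ok],
                                       onset_s = onsets[ok]),
                   valid = valid, reason = reason),
              class = "WaveFit")
  }
  if (sum(ok) < 5L) return(mkfit(FALSE, "fewer than 5 bins with threshold crossing"))
  x <- onsets[ok]; y <- kymo$bin_centers_um[ok]
  if (diff(range(x)) < 2 * kymo$dt) return(mkfit(FALSE, "synchronous onset (spread < 2 frames)"))
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- fit$residuals
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  v <- unname(fit$coefficients[2])
  if (r2 < 0.5) return(mkfit(FALSE, "poor linear fit (r^2 < 0.5)", v, r2))
  mkfit(TRUE, "ok", v, r2)
}

#' Motion maps for kymograph input from dense flow norms
#'
#' Computes a consecutive-frame displacement field and returns per-frame
#' per-pixel vector norms as an H x W x (T-1) stack, the continuous-valued
#' alternative to [windowed_mse_motion()] maps.
#'
#' @param stack H x W x T array
#' @param config [registration_config()] (forced to consecutive mode)
#' @return H x W x (T-1) array of displacement norms (px)
#' @export
flow_norm_maps <- function(stack, config = registration_config("consecutive")) {
  config$reference_mode <- "consecutive"
  field <- estimate_displacement(stack, config)
  d <- dim(stack)
  out <- array(0, c(d[1], d[2], d[3] - 1L))
  for (i in 2:d[3]) {
    out[, , i - 1L] <- sqrt(field$dx[, , i]^2 + field$dy[, , i]^2)
  }
  out
}
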