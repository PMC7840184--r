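# Whole-mount transport analysis: equidistant ROI partition around a focal
# stimulation zone, per-ROI motion AUC vs basal, directionality index.

#' Staged tubule geometry
#'
#' @param centerline n x 2 matrix of (x, y) polyline vertices, 0-based pixel
#'   coordinates, n >= 2
#' @param stim_center_um arc-length position of the stimulation-zone center
#'   (um from the first vertex)
#' @param section_um section length (um); by convention equal to the
#'   stimulation-zone length, so ROI 0 is the directly perfused area. The
#'   physical section length is an experiment-design input, not inferred.
#' @param width_um band width (um), normally the tubule diameter
#' @param ascending direction of ascending spermatogenic stages along the
#'   centerline: "increasing" (toward larger arc length) or "decreasing";
#'   always an input — stages are determined visually, never from images
#' @param stage_map optional data.frame(start_um, end_um, stage) assigning
#'   stage groups ("I", "II", "III") to arc-length intervals
#' @param pixel_size microns per pixel
#' @export
StagedTubule <- function(centerline, stim_center_um, section_um, width_um,
                         ascending = c("increasing", "decreasing"),
                         stage_map = NULL, pixel_size = 1) {
  if (identical(ascending, "+x")) ascending <- "increasing"
  ascending <- match.arg(ascending)
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2L || ncol(centerline) != 2L) {
    stop("centerline needs >= 2 (x, y) vertices")
  }
  if (section_um <= 0 || width_um <= 0) stop("section_um and width_um must be > 0")
  structure(list(centerline = centerline, stim_center_um = stim_center_um,
                 section_um = section_um, width_um = width_um,
                 ascending = ascending, stage_map = stage_map,
                 pixel_size = pixel_size),
            class = "StagedTubule")
}

# Arc-length projection of pixel centers onto a polyline. Returns, per
# pixel: s (arc length, px, of the closest point) and d (distance, px).
project_to_polyline <- function(centerline, H, W) {
  px <- rep(seq_len(W) - 1, each = H)
  py <- rep(seq_len(H) - 1, W)
  nseg <- nrow(centerline) - 1L
  seg_len <- sqrt(rowSums((centerline[-1, , drop = FALSE] -
                           centerline[-nrow(centerline), , drop = FALSE])^2))
  s0 <- c(0, cumsum(seg_len))
  best_d2 <- rep(Inf, H * W)
  best_s <- rep(0, H * W)
  for (i in seq_len(nseg)) {
    ax <- centerline[i, 1]; ay <- centerline[i, 2]
    bx <- centerline[i + 1, 1]; by <- centerline[i + 1, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    tt <- if (L2 == 0) rep(0, H * W) else pmin(pmax(((px - ax) * vx + (py - ay) * vy) / L2, 0), 1)
    d2 <- (px - (ax + tt * vx))^2 + (py - (ay + tt * vy))^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- s0[i] + tt[upd] * sqrt(L2)
  }
  list(s = best_s, d = sqrt(best_d2), total = s0[nseg + 1L])
}

#' Partition a tubule band into equidistant ROI sections
#'
#' ROI 0 is centered on the stimulation zone; sections of equal arc length
#' extend to ROI +/-k, positive indices on the ascending-stage side. Masks
#' are obtained by binning each band pixel's arc-length projection, so the
#' sections tile the band exactly (no overlaps, no gaps). If the centerline
#' is too short for 2k+1 sections, the missing ROIs are dropped with a
#' warning.
#'
#' @param tubule [StagedTubule]
#' @param k sections per side (the whole-mount layout used up to 6)
#' @param shape image dims c(H, W)
#' @return list of [Roi]-like objects ordered by index -k..k (field `index`)
#' @export
partition_rois <- function(tubule, k = 6L, shape) {
  H <- shape[1]; W <- shape[2]
  pxsz <- tubule$pixel_size
  sec_px <- tubule$section_um / pxsz
  half_w <- tubule$width_um / (2 * pxsz)
  proj <- project_to_polyline(tubule$centerline, H, W)
  s_center <- tubule$stim_center_um / pxsz
  sgn <- if (tubule$ascending == "increasing") 1 else -1
  rel <- sgn * (proj$s - s_center) / sec_px
  idx <- floor(rel + 0.5)
  in_band <- proj$d <= half_w &
    proj$s > 1e-9 & proj$s < proj$total - 1e-9   # drop beyond-endpoint pixels
  rois <- list()
  dropped <- integer(0)
  for (i in (-k):k) {
    mask <- matrix(in_band & idx == i, H, W)
    if (!any(mask)) { dropped <- c(dropped, i); next }
    roi <- roi_from_mask(sprintf("ROI %d", i), mask,
                         polygon = section_outline(tubule, i, sgn, shape))
    roi$index <- i
    roi$stage <- stage_at(tubule, tubule$stim_center_um + sgn * i * tubule$section_um)
    rois[[length(rois) + 1L]] <- roi
  }
  if (length(dropped)) {
    warning("centerline too short for ROI(s): ",
            paste(sprintf("%+d", dropped), collapse = ", "))
  }
  rois
}

# Build a Roi-like object directly from a mask (mask is authoritative; the
# polygon is a serializable outline approximation).
roi_from_mask <- function(label, mask, polygon = NULL) {
  if (is.null(polygon)) {
    w <- which(mask, arr.ind = TRUE)
    polygon <- cbind(
      x = c(min(w[, 2]), max(w[, 2]), max(w[, 2]), min(w[, 2])) - 1,
      y = c(min(w[, 1]), min(w[, 1]), max(w[, 1]), max(w[, 1])) - 1
    )
  }
  structure(list(label = label, polygon = polygon, mask = mask,
                 index = parse_roi_index(label)),
            class = "Roi")
}

# Outline polygon for section i: centerline strip offset by +/- width/2.
section_outline <- function(tubule, i, sgn, shape) {
  pxsz <- tubule$pixel_size
  sec_px <- tubule$section_um / pxsz
  half_w <- tubule$width_um / (2 * pxsz)
  s_center <- tubule$stim_center_um / pxsz
  lo <- s_center + sgn * i * sec_px - sec_px / 2
  hi <- lo + sec_px
  cl <- tubule$centerline
  seg_len <- sqrt(rowSums((cl[-1, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE])^2))
  s0 <- c(0, cumsum(seg_len))
  ss <- seq(max(lo, 0), min(hi, s0[length(s0)]), length.out = 12)
  pt <- function(s) {
    j <- max(1L, min(findInterval(s, s0), length(seg_len)))
    tt <- if (seg_len[j] == 0) 0 else (s - s0[j]) / seg_len[j]
    p <- cl[j, ] + tt * (cl[j + 1L, ] - cl[j, ])
    tg <- (cl[j + 1L, ] - cl[j, ]) / max(seg_len[j], 1e-9)
    list(p = p, n = c(-tg[2], tg[1]))
  }
  up <- t(vapply(ss, function(s) { q <- pt(s); q$p + half_w * q$n }, numeric(2)))
  dn <- t(vapply(rev(ss), function(s) { q <- pt(s); q$p - half_w * q$n }, numeric(2)))
  poly <- rbind(up, dn)
  poly[, 1] <- pmin(pmax(poly[, 1], 0), shape[2] - 1)
  poly[, 2] <- pmin(pmax(poly[, 2], 0), shape[1] - 1)
  poly
}

# Stage group at an arc-length position, from the tubule's stage_map.
stage_at <- function(tubule, s_um) {
  sm <- tubule$stage_map
  if (is.null(sm)) return(NA_character_)
  hit <- which(s_um >= sm$start_um & s_um < sm$end_um)
  if (length(hit)) as.character(sm$stage[hit[1]]) else NA_character_
}

#' Per-ROI transport profile around the stimulation zone
#'
#' Computes, for every ROI section, the AUC of the (rectified) flow-change
#' series over the post-onset window and the equal-length basal AUC before
#' onset, from a consecutive-frame displacement field of the brightfield
#' channel.
#'
#' @param rec [TimeLapseRecording] with a brightfield channel (or an
#'   H x W x T array)
#' @param rois ROI list from [partition_rois()]
#' @param protocol [StimulusProtocol]
#' @param window_s AUC window (s), default the standard 60 s
#' @param smoothing_window moving-average window for the s series
#' @param config [registration_config()]; reference mode is forced to
#'   "consecutive" (luminal motion is frame-to-frame, not cumulative)
#' @param field optional precomputed [DisplacementField] (skips estimation)
#' @param rectify integrate |c| (default TRUE)
#' @return object of class `TransportProfile`: data.frame with columns
#'   roi_index, stage, auc, basal, plus attribute `di` (the directionality
#'   index) accessible via [directionality_index()]
#' @export
transport_profile <- function(rec, rois, protocol, window_s = 60,
                              smoothing_window = 5L,
                              config = registration_config("consecutive"),
                              field = NULL, rectify = TRUE) {
  stack <- if (inherits(rec, "TimeLapseRecording")) get_channel(rec, "brightfield") else rec
  dt <- if (inherits(rec, "TimeLapseRecording")) rec$dt else 1
  if (is.null(field)) {
    config$reference_mode <- "consecutive"
    field <- estimate_displacement(stack, config)
  }
  Tn <- dim(stack)[3]
  times <- (seq_len(Tn) - 1) * dt
  onset <- protocol$onsets[1]
  rows <- lapply(rois, function(roi) {
    mr <- quantify_motion(field, roi, times, onset, window_s = window_s,
                          smoothing_window = smoothing_window, rectify = rectify)
    data.frame(roi_index = roi$index,
               stage = if (is.null(roi$stage)) NA_character_ else roi$stage,
               auc = mr$auc_post, basal = mr$auc_basal,
               stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, rows)
  prof <- prof[order(prof$roi_index), ]
  rownames(prof) <- NULL
  class(prof) <- c("TransportProfile", "data.frame")
  prof
}

#' Directionality index of a transport profile
#'
#' DI = (A+ - A-) / (A+ + A-), where A+- sums the supra-basal rectified
#' excess max(auc - basal, 0) over the ROIs of each side (basal luminal
#' motion exists before stimulation and must not contribute). DI is +1 when
#' all supra-basal motion lies on the ascending side, -1 on the descending
#' side, and 0 for a symmetric profile or when no ROI exceeds basal.
#'
#' @param profile [transport_profile()] output (needs >= 1 ROI per side)
#' @return DI in [-1, 1]
#' @export
directionality_index <- function(profile) {
  pos <- profile$roi_index > 0
  neg <- profile$roi_index < 0
  if (!any(pos) || !any(neg)) stop("need at least one ROI on each side")
  excess <- pmax(profile$auc - profile$basal, 0)
  a_pos <- sum(excess[pos]); a_neg <- sum(excess[neg])
  if (a_pos + a_neg == 0) return(0)
  (a_pos - a_neg) / (a_pos + a_neg)
}
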