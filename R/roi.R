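#' Region of interest defined by a polygon
#'
#' Polygons use the on-disk convention: vertices are `(x, y)` pairs in
#' 0-based pixel-center coordinates (x = column, y = row). The rasterized
#' mask marks every pixel whose center lies inside the polygon under the
#' even-odd rule; centers exactly on an edge count as inside, so an
#' axis-aligned square from (0,0) to (4,4) covers a 5 x 5 pixel block.
#'
#' @param label ROI label, e.g. "ROI 0" or "ROI -3"
#' @param polygon n x 2 matrix (or list of `[x, y]` pairs) of vertices, n >= 3
#' @param shape image dimensions `c(H, W)` used to rasterize the mask
#' @return object of class `Roi` with fields `label`, `polygon`, `mask`
#'   (logical H x W) and `index` (numeric index parsed from "ROI k" labels,
#'   NA otherwise)
#' @export
Roi <- function(label, polygon, shape) {
  if (is.list(polygon)) polygon <- do.call(rbind, lapply(polygon, as.numeric))
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L) {
    stop("polygon must have >= 3 (x, y) vertices")
  }
  if (any(!is.finite(polygon))) stop("polygon vertices must be finite")
  H <- shape[1]; W <- shape[2]
  if (any(polygon[, 1] < -0.5) || any(polygon[, 1] > W - 0.5) ||
      any(polygon[, 2] < -0.5) || any(polygon[, 2] > H - 0.5)) {
    stop("polygon extends outside the image bounds")
  }
  mask <- rasterize_polygon(polygon, H, W)
  if (!any(mask)) stop("polygon encloses no pixel centers (empty mask)")
  structure(
    list(label = label, polygon = polygon, mask = mask, index = parse_roi_index(label)),
    class = "Roi"
  )
}

# "ROI -3" -> -3; anything unparseable -> NA
parse_roi_index <- function(label) {
  m <- regmatches(label, regexpr("-?[0-9]+", label))
  if (length(m) == 0L) NA_real_ else as.numeric(m)
}

#' Even-odd polygon rasterization over pixel centers
#'
#' @param polygon n x 2 matrix of (x, y) vertices, 0-based pixel centers
#' @param H,W image dimensions
#' @return logical H x W mask
#' @keywords internal
rasterize_polygon <- function(polygon, H, W) {
  px <- rep(seq_len(W) - 1, each = H)   # x of every pixel center, column-major
  py <- rep(seq_len(H) - 1, W)
  n <- nrow(polygon)
  inside <- rep(FALSE, H * W)
  on_edge <- rep(FALSE, H * W)
  j <- n
  for (i in seq_len(n)) {
    xi <- polygon[i, 1]; yi <- polygon[i, 2]
    xj <- polygon[j, 1]; yj <- polygon[j, 2]
    # even-odd crossing test (half-open rule on y)
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      inside <- xor(inside, crosses & (px < xint))
    }
    # boundary inclusion: point on the closed segment [i, j]
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx^2 + dy^2
    if (len2 == 0) {
      on_edge <- on_edge | (abs(px - xi) < 1e-9 & abs(py - yi) < 1e-9)
    } else {
      tt <- ((px - xi) * dx + (py - yi) * dy) / len2
      cross <- (px - xi) * dy - (py - yi) * dx
      on_edge <- on_edge | (abs(cross) < 1e-9 * sqrt(len2) & tt >= -1e-12 & tt <= 1 + 1e-12)
    }
    j <- i
  }
  matrix(inside | on_edge, H, W)
}

#' Read ROI definitions from JSON
#'
#' Schema: `{"rois": [{"label": "ROI 0", "polygon": [[x, y], ...]}, ...]}`
#' with 0-based pixel-center coordinates. ROIs whose labels carry an integer
#' index ("ROI -6" .. "ROI 6") are returned ordered by that index.
#'
#' @param path JSON file path
#' @param shape image dimensions `c(H, W)`
#' @return list of [Roi] objects
#' @export
read_rois <- function(path, shape) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$rois) || length(doc$rois) == 0L) stop("no 'rois' array in ", path)
  rois <- lapply(doc$rois, function(r) Roi(r$label, r$polygon, shape))
  idx <- vapply(rois, function(r) r$index, numeric(1))
  if (!any(is.na(idx))) rois <- rois[order(idx)]
  rois
}

#' Write ROI definitions to JSON (inverse of [read_rois()])
#' @param rois list of [Roi] objects
#' @param path output JSON path
#' @export
write_rois <- function(rois, path) {
  doc <- list(rois = lapply(rois, function(r) {
    list(label = r$label,
         polygon = lapply(seq_len(nrow(r$polygon)), function(i) unname(r$polygon[i, ])))
  }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
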