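# Low-level image helpers shared across modules.
#
# Conventions (package-wide):
#  * a frame is an H x W numeric matrix; row index = y, column index = x
#  * a stack is an H x W x T numeric array
#  * internal coordinates are 1-based pixel centers; the on-disk ROI JSON
#    schema is 0-based (see read_rois) and converted at the boundary
#  * displacement components: dx along columns (x), dy along rows (y)

#' Normalized 1-D Gaussian kernel truncated at 3 sigma
#' @param sigma standard deviation in pixels (0 returns the identity kernel)
#' @return numeric vector of odd length summing to 1
#' @keywords internal
gauss_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Integer shift with replicate (edge-clamp) padding.
# dy > 0 moves content down, dx > 0 moves content right, i.e.
# out[r, c] = m[clamp(r - dy), clamp(c - dx)].
shift_int <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) - dy, 1L), H)
  ci <- pmin(pmax(seq_len(W) - dx, 1L), W)
  m[ri, ci, drop = FALSE]
}

# Separable 1-D convolution along rows (dim = 1, i.e. along y) or columns
# (dim = 2, along x) with replicate padding; kernel must be odd-length.
conv1_replicate <- function(m, k, dim) {
  L <- length(k)
  if (L == 1L) return(m * k)
  r <- (L - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_len(L)) {
    off <- j - r - 1L
    out <- out + k[j] * if (dim == 1L) shift_int(m, -off, 0L) else shift_int(m, 0L, -off)
  }
  out
}

#' 2-D Gaussian blur (separable, replicate padding)
#' @keywords internal
gauss_blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gauss_kernel1d(sigma)
  conv1_replicate(conv1_replicate(m, k, 1L), k, 2L)
}

# Apply a function frame-wise over an H x W x T stack.
stack_map <- function(stack, f) {
  out <- stack
  for (t in seq_len(dim(stack)[3])) out[, , t] <- f(stack[, , t])
  out
}

# Temporal 1-D convolution (along the T axis) with replicate padding.
conv_temporal <- function(stack, k) {
  L <- length(k)
  if (L == 1L) return(stack * k)
  d <- dim(stack)
  Tn <- d[3]
  r <- (L - 1L) %/% 2L
  m <- matrix(stack, nrow = d[1] * d[2], ncol = Tn)
  out <- matrix(0, nrow(m), Tn)
  idx <- seq_len(Tn)
  for (j in seq_len(L)) {
    off <- j - r - 1L
    ti <- pmin(pmax(idx + off, 1L), Tn)
    out <- out + k[j] * m[, ti, drop = FALSE]
  }
  array(out, dim = d)
}

#' Bilinear sampling with edge clamping
#'
#' Samples `img` at fractional 1-based coordinates; coordinates outside the
#' image are clamped to the border (replicate padding).
#' @param img H x W matrix
#' @param x,y numeric vectors of column / row coordinates
#' @keywords internal
bilinear_sample <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  x <- pmin(pmax(x, 1), W)
  y <- pmin(pmax(y, 1), H)
  x0 <- pmin(floor(x), W - 1L); y0 <- pmin(floor(y), H - 1L)
  if (W == 1L) x0 <- rep(1, length(x))
  if (H == 1L) y0 <- rep(1, length(y))
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1L, W); y1 <- pmin(y0 + 1L, H)
  i00 <- (x0 - 1) * H + y0
  i01 <- (x1 - 1) * H + y0
  i10 <- (x0 - 1) * H + y1
  i11 <- (x1 - 1) * H + y1
  v <- img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
  v
}

# Warp a frame by a displacement field: out[r, c] = img[r + dy, c + dx]
# (bilinear, replicate padding). dx/dy are H x W matrices or scalars.
warp_frame <- function(img, dx, dy) {
  H <- nrow(img); W <- ncol(img)
  cc <- matrix(rep(seq_len(W), each = H), H, W)
  rr <- matrix(rep(seq_len(H), W), H, W)
  matrix(bilinear_sample(img, as.vector(cc + dx), as.vector(rr + dy)), H, W)
}

# Resize a matrix to H2 x W2 by bilinear interpolation over pixel centers.
resize_bilinear <- function(m, H2, W2) {
  H <- nrow(m); W <- ncol(m)
  y <- if (H2 == 1L) (H + 1) / 2 else 1 + (seq_len(H2) - 1) * (H - 1) / (H2 - 1)
  x <- if (W2 == 1L) (W + 1) / 2 else 1 + (seq_len(W2) - 1) * (W - 1) / (W2 - 1)
  cc <- rep(x, each = H2)
  rr <- rep(y, W2)
  matrix(bilinear_sample(m, cc, rr), H2, W2)
}

# One pyramid reduction: Gaussian pre-smooth then 2x decimation.
pyr_down <- function(m) {
  s <- gauss_blur2d(m, 1)
  s[seq(1, nrow(m), by = 2L), seq(1, ncol(m), by = 2L), drop = FALSE]
}

#' Centered moving average with shrinking windows at the edges
#' @param x numeric vector
#' @param window odd integer window length (1 = identity)
#' @keywords internal
moving_average <- function(x, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1L) return(x)
  n <- length(x)
  r <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - r, 1L)
  hi <- pmin(seq_len(n) + r, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

# Linear interpolation of a series at time t (clamped).
interp_at <- function(times, values, t) {
  stats::approx(times, values, xout = t, rule = 2)$y
}
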