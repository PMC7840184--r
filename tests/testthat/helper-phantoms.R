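# Shared fixtures, all generated in code.

# Band-limited random texture that can be evaluated at arbitrary (possibly
# shifted) coordinates WITHOUT interpolation: a sum of 2-D sinusoids. This
# gives exact subpixel ground truth independent of the package's warping.
sin_texture <- function(H, W, seed = 1, n_waves = 12, amplitude = 40,
                        offset = 100) {
  set.seed(seed)
  kx <- runif(n_waves, -pi / 3, pi / 3)
  ky <- runif(n_waves, -pi / 3, pi / 3)
  ph <- runif(n_waves, 0, 2 * pi)
  a <- runif(n_waves, 0.4, 1)
  f <- function(dx = 0, dy = 0) {
    xx <- matrix(rep(seq_len(W), each = H), H, W) - dx
    yy <- matrix(rep(seq_len(H), W), H, W) - dy
    m <- matrix(offset, H, W)
    for (j in seq_len(n_waves)) {
      m <- m + amplitude * a[j] * sin(kx[j] * xx + ky[j] * yy + ph[j])
    }
    m
  }
  f
}

# Two-frame stack: frame 2 is frame 1 with content moved by +(dx, dy).
shifted_pair_stack <- function(H, W, dx, dy, seed = 1, noise_sd = 0) {
  tex <- sin_texture(H, W, seed = seed)
  a <- tex(0, 0); b <- tex(dx, dy)
  if (noise_sd > 0) {
    a <- a + matrix(rnorm(H * W, sd = noise_sd), H, W)
    b <- b + matrix(rnorm(H * W, sd = noise_sd), H, W)
  }
  array(c(a, b), c(H, W, 2))
}

# Brute-force even-odd point-in-polygon (independent of the package's
# rasterizer): crossing-number test per pixel center, boundary-inclusive.
brute_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  cross <- 0L
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-edge check
    dx <- xj - xi; dy <- yj - yi
    L2 <- dx^2 + dy^2
    if (L2 == 0) {
      if (px == xi && py == yi) return(TRUE)
    } else {
      tt <- ((px - xi) * dx + (py - yi) * dy) / L2
      cr <- (px - xi) * dy - (py - yi) * dx
      if (abs(cr) < 1e-9 * sqrt(L2) && tt >= 0 && tt <= 1) return(TRUE)
    }
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      if (px < xint) cross <- cross + 1L
    }
  }
  cross %% 2L == 1L
}

brute_rasterize <- function(poly, H, W) {
  m <- matrix(FALSE, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    m[r, c] <- brute_point_in_polygon(c - 1, r - 1, poly)
  }
  m
}

# Random convex polygon (points on a noisy ellipse, ordered by angle).
random_convex_polygon <- function(H, W, seed) {
  set.seed(seed)
  n <- sample(3:8, 1)
  ang <- sort(runif(n, 0, 2 * pi))
  cx <- runif(1, W * 0.3, W * 0.7); cy <- runif(1, H * 0.3, H * 0.7)
  rad <- runif(1, min(H, W) * 0.15, min(H, W) * 0.35)
  cbind(x = cx + rad * cos(ang), y = cy + rad * sin(ang))
}

# Brute-force Gaussian-window MSE motion oracle: per-pixel loops, explicit
# Gaussian weights, replicate-clamped sampling of the per-shift difference
# image (same boundary semantics as the vectorized implementation, computed
# a completely different way).
brute_windowed_mse <- function(prev, cur, sigma, max_distance) {
  H <- nrow(prev); W <- ncol(prev)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  off <- (-r):r
  w1 <- exp(-off^2 / (2 * sigma^2)); w1 <- w1 / sum(w1)
  wmat <- outer(w1, w1)
  shifts <- expand.grid(dy = (-max_distance):max_distance,
                        dx = (-max_distance):max_distance)
  nrm <- sqrt(shifts$dx^2 + shifts$dy^2)
  ord <- order(nrm, shifts$dy, shifts$dx)
  shifts <- shifts[ord, ]; nrm <- nrm[ord]
  clampr <- function(i) pmin(pmax(i, 1L), H)
  clampc <- function(i) pmin(pmax(i, 1L), W)
  out <- matrix(0, H, W)
  for (p_r in seq_len(H)) for (p_c in seq_len(W)) {
    rr <- clampr(p_r + off); cc <- clampc(p_c + off)
    Cw <- cur[rr, cc]
    best <- Inf; bestn <- 0
    for (s in seq_len(nrow(shifts))) {
      Pw <- prev[clampr(rr - shifts$dy[s]), clampc(cc - shifts$dx[s])]
      acc <- sum(wmat * (Cw - Pw)^2)
      if (acc < best) { best <- acc; bestn <- nrm[s] }
    }
    out[p_r, p_c] <- bestn
  }
  out
}
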