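# Synthetic phantom movies with exact ground truth.
#
# Every generator renders frames analytically (soft, area-weighted edges, so
# subpixel displacements are representable) and records the quantities the
# downstream analyses are supposed to recover. Fixed seed => bit-identical
# output.

# Evaluate code with a temporary RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Phantom generation parameters
#'
#' Defaults emulate the acute-slice recording regime: 1 Hz acquisition, a
#' tubule of ~40 um diameter in a 64 x 64 field at 1 um/px, a single
#' stimulus at t = 10 s, contraction peaking a few micrometres inward with
#' exponential rise/decay, and a calcium transient that leads the
#' contraction by `coupling_delay_s`.
#'
#' @param H,W image dimensions (px)
#' @param n_frames number of frames
#' @param dt frame interval (s)
#' @param pixel_size microns per pixel
#' @param radius_um tubule outer radius (um)
#' @param wall_um wall thickness (um)
#' @param amplitude_um peak inward contraction displacement (um); must be
#'   smaller than `radius_um`
#' @param onset_s contraction onset time (s)
#' @param rise_tau_s,decay_tau_s single-exponential rise / decay time
#'   constants of the contraction and calcium kinetics (s)
#' @param ca_amplitude peak dF/F of the calcium transient (dimensionless)
#' @param coupling_delay_s delay from calcium onset to contraction onset (s);
#'   the calcium transient starts at `onset_s - coupling_delay_s`
#' @param wave_velocity_um_s contraction wave propagation velocity for
#'   [make_wave_movie()] (um/s; sign = direction along the tubule axis)
#' @param noise_sd Gaussian camera noise SD (intensity units; 0 = clean)
#' @param seed RNG seed; fixed seed gives bit-identical stacks
#' @return list of class `PhantomParams`
#' @export
phantom_params <- function(H = 64L, W = 64L, n_frames = 60L, dt = 1,
                           pixel_size = 1, radius_um = 22, wall_um = 7,
                           amplitude_um = 4, onset_s = 10, rise_tau_s = 2,
                           decay_tau_s = 10, ca_amplitude = 0.5,
                           coupling_delay_s = 1, wave_velocity_um_s = 50,
                           noise_sd = 0, seed = 1L) {
  p <- list(H = as.integer(H), W = as.integer(W), n_frames = as.integer(n_frames),
            dt = dt, pixel_size = pixel_size, radius_um = radius_um,
            wall_um = wall_um, amplitude_um = amplitude_um, onset_s = onset_s,
            rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
            ca_amplitude = ca_amplitude, coupling_delay_s = coupling_delay_s,
            wave_velocity_um_s = wave_velocity_um_s, noise_sd = noise_sd,
            seed = as.integer(seed))
  num <- c("dt", "pixel_size", "radius_um", "wall_um", "amplitude_um",
           "rise_tau_s", "decay_tau_s", "ca_amplitude", "noise_sd")
  for (f in num) if (p[[f]] < 0) stop("phantom parameter '", f, "' must be >= 0")
  if (p$dt <= 0 || p$pixel_size <= 0) stop("dt and pixel_size must be > 0")
  class(p) <- "PhantomParams"
  p
}

# Normalized transient kinetics: 0 before onset, single-exponential rise and
# decay after, peak exactly 1.
transient_kinetics <- function(t, onset, rise_tau, decay_tau) {
  d <- t - onset
  k <- ifelse(d <= 0, 0, (1 - exp(-d / max(rise_tau, 1e-9))) * exp(-d / max(decay_tau, 1e-9)))
  dpk <- rise_tau * log1p(decay_tau / max(rise_tau, 1e-9))
  pk <- (1 - exp(-dpk / max(rise_tau, 1e-9))) * exp(-dpk / max(decay_tau, 1e-9))
  if (pk <= 0) return(k * 0)
  k / pk
}

# Soft (area-weighted) band indicator: 1 inside [lo, hi], linear 1-px ramps.
soft_band <- function(x, lo, hi) {
  v <- pmax(0, pmin(1, x - lo + 0.5)) * pmax(0, pmin(1, hi - x + 0.5))
  dim(v) <- dim(x)   # pmax(0, m) drops matrix dims
  v
}

#' Contracting-annulus phantom with coupled calcium transient
#'
#' Renders a tubule cross-section (annulus) whose wall shifts radially
#' inward with the configured kinetics, a textured brightfield channel for
#' registration, and a GCaMP-style fluorescence channel carrying a dF/F
#' transient in the wall band that precedes the contraction by the coupling
#' delay. Optionally renders a fura-2 excitation pair instead of GCaMP.
#'
#' @param params [phantom_params()]
#' @param channels subset of c("brightfield", "gcamp", "f340", "f380")
#' @return list with `recording` ([TimeLapseRecording]) and `truth`, a
#'   `GroundTruth` list carrying: `displacement` (dx/dy arrays of the true
#'   t0-referenced field on the wall band), `s` (true flow strength =
#'   displacement magnitude per frame, px), `ca_trace` (true dF/F trace),
#'   `wall_mask` (t0 wall band), `edge_displacement_px` per frame, and the
#'   generating params
#' @export
make_contracting_tubule <- function(params = phantom_params(),
                                    channels = c("brightfield", "gcamp")) {
  p <- params
  if (p$amplitude_um >= p$radius_um) stop("contraction amplitude must be < radius")
  px <- p$pixel_size
  R <- p$radius_um / px; wall <- p$wall_um / px; A <- p$amplitude_um / px
  H <- p$H; W <- p$W
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rr <- matrix(rep(seq_len(H), W), H, W) - cy
  cc <- matrix(rep(seq_len(W), each = H), H, W) - cx
  r <- sqrt(rr^2 + cc^2)
  theta <- atan2(rr, cc)
  times <- (seq_len(p$n_frames) - 1) * p$dt
  k_con <- transient_kinetics(times, p$onset_s, p$rise_tau_s, p$decay_tau_s)
  k_ca <- transient_kinetics(times, p$onset_s - p$coupling_delay_s,
                             p$rise_tau_s, p$decay_tau_s)
  d_px <- A * k_con

  # angular + radial texture in material coordinates (moves with the wall)
  tex_fun <- function(rho) {
    1 + 0.35 * sin(5 * theta + 1.3) + 0.25 * sin(9 * theta - 0.4) +
      0.2 * sin(2 * pi * rho / 5.3) * cos(3 * theta)
  }
  wall_lo <- R - wall; wall_hi <- R

  out <- list()
  for (ch in channels) out[[ch]] <- array(0, c(H, W, p$n_frames))
  for (i in seq_len(p$n_frames)) {
    rho <- r + d_px[i]              # material radius: where this pixel was at t0
    cov <- soft_band(rho, wall_lo, wall_hi)
    if ("brightfield" %in% channels) {
      out$brightfield[, , i] <- 30 + 90 * cov * tex_fun(rho)
    }
    if ("gcamp" %in% channels) {
      # small dark offset: a large camera offset would attenuate measured
      # dF/F below the configured indicator amplitude
      out$gcamp[, , i] <- 2 + 80 * cov * (1 + p$ca_amplitude * k_ca[i])
    }
    if ("f340" %in% channels) {
      out$f340[, , i] <- 10 + 70 * cov * (1 + 0.8 * p$ca_amplitude * k_ca[i])
    }
    if ("f380" %in% channels) {
      out$f380[, , i] <- 10 + 90 * cov * (1 - 0.4 * p$ca_amplitude * k_ca[i])
    }
  }
  if (p$noise_sd > 0) {
    out <- with_seed(p$seed, {
      for (ch in names(out)) {
        out[[ch]] <- pmax(out[[ch]] + array(stats::rnorm(length(out[[ch]]),
                                                         sd = p$noise_sd),
                                            dim(out[[ch]])), 0)
      }
      out
    })
  }

  wall_mask <- soft_band(r, wall_lo, wall_hi) >= 0.5
  dx <- array(0, c(H, W, p$n_frames)); dy <- dx
  runit_x <- ifelse(r > 1e-9, cc / r, 0)
  runit_y <- ifelse(r > 1e-9, rr / r, 0)
  for (i in seq_len(p$n_frames)) {
    # material at t0 pixel (r, theta) sits at radius r - d at t_i, so the
    # t0-referenced field (ref(p) = frame_i(p + v)) points inward
    dx[, , i] <- -d_px[i] * runit_x * wall_mask
    dy[, , i] <- -d_px[i] * runit_y * wall_mask
  }
  truth <- structure(list(
    displacement = list(dx = dx, dy = dy),
    s = d_px,
    ca_trace = p$ca_amplitude * k_ca,
    ca_kinetics = k_ca,
    wall_mask = wall_mask,
    edge_displacement_px = d_px,
    times = times,
    params = p
  ), class = "GroundTruth")
  list(recording = TimeLapseRecording(out, dt = p$dt, pixel_size = p$pixel_size),
       truth = truth)
}

#' Propagating contraction-wave phantom
#'
#' A straight horizontal tubule whose local contraction onset is delayed
#' linearly along the axis: onset(x) = onset_s + (x - x_entry) / |v|, with
#' the entry end chosen by the sign of `wave_velocity_um_s`. The truth
#' records the configured velocity and per-column onset times.
#'
#' @param params [phantom_params()]; `wave_velocity_um_s` must be non-zero
#' @param length_um tubule length (um); the supported range in this kind of
#'   preparation spans roughly 200 um to a few mm
#' @return list with `recording` (brightfield channel) and `truth`
#'   (`velocity_um_s`, `onset_s` per column, `x_um` column positions)
#' @export
make_wave_movie <- function(params = phantom_params(), length_um = 500) {
  p <- params
  v <- p$wave_velocity_um_s
  if (v == 0) stop("wave velocity must be non-zero")
  px <- p$pixel_size
  Lpx <- round(length_um / px)
  if (length_um < 10 * p$radius_um) stop("tubule length must be >= 10 x radius")
  W <- as.integer(Lpx)
  H <- p$H
  R <- p$radius_um / px; wall <- p$wall_um / px; A <- p$amplitude_um / px
  cy <- (H + 1) / 2
  if (2 * (R + 1) > H) stop("tubule diameter exceeds image height")
  times <- (seq_len(p$n_frames) - 1) * p$dt
  x_um <- (seq_len(W) - 0.5) * px
  onset_x <- if (v > 0) p$onset_s + (x_um - x_um[1]) / v
             else p$onset_s + (x_um[W] - x_um) / abs(v)
  spread <- diff(range(onset_x))
  resolvable <- spread >= 2 * p$dt
  if (!resolvable) warning("onset spread < 2 frames: wave unresolvable at this dt")

  yy <- matrix(rep(seq_len(H), W), H, W) - cy
  xtex <- matrix(rep(seq_len(W), each = H), H, W)
  rr <- abs(yy)
  texture <- 1 + 0.3 * sin(2 * pi * xtex / 7.3) + 0.25 * sin(2 * pi * yy / 5.1 + 1.0) +
    0.2 * sin(2 * pi * (xtex + yy) / 11.7)
  stack <- array(0, c(H, W, p$n_frames))
  for (i in seq_len(p$n_frames)) {
    k_i <- transient_kinetics(rep(times[i], W), onset_x, p$rise_tau_s, p$decay_tau_s)
    d <- matrix(rep(A * k_i, each = H), H, W)
    rho <- rr + d                    # walls move inward (toward the axis)
    cov <- soft_band(rho, R - wall, R)
    stack[, , i] <- 25 + 95 * cov * texture
  }
  if (p$noise_sd > 0) {
    stack <- with_seed(p$seed, pmax(stack + array(stats::rnorm(length(stack),
                                                               sd = p$noise_sd),
                                                  dim(stack)), 0))
  }
  truth <- structure(list(
    velocity_um_s = v, onset_s = onset_x, x_um = x_um,
    resolvable = resolvable, times = times, params = p
  ), class = "GroundTruth")
  list(recording = TimeLapseRecording(list(brightfield = stack), dt = p$dt,
                                      pixel_size = p$pixel_size),
       truth = truth)
}

#' Per-ROI advection speed profiles for transport phantoms
#'
#' @param kind "roi0" (advection only in the stimulated section),
#'   "symmetric" (equal propagation to both sides) or "ascending"
#'   (supra-basal motion only on the ascending-stage side)
#' @param k number of sections on each side of ROI 0
#' @param v0 peak advection speed in ROI 0 (um/s)
#' @param reach how many sections the motion propagates into (geometric
#'   falloff 0.6 per section)
#' @return named numeric vector of speeds, names "-k" .. "k"
#' @export
advection_profile <- function(kind = c("ascending", "symmetric", "roi0"),
                              k = 3L, v0 = 8, reach = 2L) {
  kind <- match.arg(kind)
  idx <- (-k):k
  sp <- numeric(2 * k + 1)
  names(sp) <- as.character(idx)
  sp["0"] <- v0
  fall <- function(i) v0 * 0.6^i
  for (i in seq_len(min(k, reach))) {
    if (kind == "symmetric") { sp[as.character(i)] <- fall(i); sp[as.character(-i)] <- fall(i) }
    if (kind == "ascending") sp[as.character(i)] <- fall(i)
  }
  sp
}

#' Luminal-transport phantom around a focal stimulation zone
#'
#' A straight horizontal tubule with static textured walls and discrete
#' luminal particles. Before the stimulus the particles only jitter (basal
#' motion); within the response window, particles advect along +x with a
#' speed set by the ROI section they currently occupy, per
#' [advection_profile()]. Returns the recording, the ROI layout (2k+1
#' equidistant sections, ROI 0 centered on the stimulation zone), the
#' stimulus protocol, and truth (profile, expected sidedness).
#'
#' @param params [phantom_params()]
#' @param profile named speed vector from [advection_profile()]
#' @param section_um section (and stimulation-zone) length (um)
#' @param n_particles luminal particle count
#' @param basal_jitter_um RMS per-frame random particle jitter (um),
#'   present throughout the recording
#' @param stim_duration_s stimulus duration (s); the whole-mount experiments
#'   used 100 uM ATP for 10 s
#' @return list with `recording`, `rois`, `protocol`, `tubule`
#'   ([StagedTubule]) and `truth`
#' @export
make_transport_movie <- function(params = phantom_params(n_frames = 140L),
                                 profile = advection_profile("ascending"),
                                 section_um = 60, n_particles = 90,
                                 basal_jitter_um = 0.3, stim_duration_s = 10) {
  p <- params
  k <- (length(profile) - 1L) %/% 2L
  px <- p$pixel_size
  sec_px <- section_um / px
  W <- as.integer(ceiling((2 * k + 1) * sec_px) + 8L)
  H <- p$H
  R <- p$radius_um / px; wall <- p$wall_um / px
  cy <- (H + 1) / 2
  x0 <- (W + 1) / 2                       # stimulation-zone center (px)
  times <- (seq_len(p$n_frames) - 1) * p$dt
  env <- transient_kinetics(times, p$onset_s, p$rise_tau_s, p$decay_tau_s)

  lum_half <- R - wall                    # lumen half-height (px)
  x_lo <- x0 - (2 * k + 1) * sec_px / 2
  x_hi <- x0 + (2 * k + 1) * sec_px / 2
  roi_index_of <- function(x) pmax(-k, pmin(k, floor((x - x0) / sec_px + 0.5)))

  yy <- matrix(rep(seq_len(H), W), H, W) - cy
  xx <- matrix(rep(seq_len(W), each = H), H, W)
  wall_cov <- soft_band(abs(yy), R - wall, R)
  wall_tex <- 1 + 0.3 * sin(2 * pi * xx / 6.7) + 0.2 * sin(2 * pi * yy / 4.9)
  base_frame <- 20 + 70 * wall_cov * wall_tex

  stack <- array(0, c(H, W, p$n_frames))
  truth_tracks <- matrix(0, n_particles, p$n_frames)
  stack <- with_seed(p$seed, {
    xp <- stats::runif(n_particles, x_lo + 2, x_hi - 2)
    yp <- stats::runif(n_particles, cy - 0.6 * lum_half, cy + 0.6 * lum_half)
    amp <- stats::runif(n_particles, 40, 80)
    jit <- basal_jitter_um / px
    for (i in seq_len(p$n_frames)) {
      if (i > 1L) {
        sp <- unname(profile[as.character(roi_index_of(xp))]) / px  # px/s
        xp <- xp + sp * env[i] * p$dt + stats::rnorm(n_particles, sd = jit)
        yp <- yp + stats::rnorm(n_particles, sd = jit / 2)
        xp <- pmin(pmax(xp, 3), W - 2)   # particles never leave the lumen
        yp <- pmin(pmax(yp, cy - lum_half + 1), cy + lum_half - 1)
      }
      truth_tracks[, i] <- xp
      fr <- base_frame
      for (j in seq_len(n_particles)) {
        r2 <- (xx - xp[j])^2 + (yy + cy - yp[j])^2
        fr <- fr + amp[j] * exp(-r2 / (2 * 1.3^2))
      }
      if (p$noise_sd > 0) {
        fr <- pmax(fr + matrix(stats::rnorm(H * W, sd = p$noise_sd), H, W), 0)
      }
      stack[, , i] <- fr
    }
    stack
  })

  rec <- TimeLapseRecording(list(brightfield = stack), dt = p$dt,
                            pixel_size = p$pixel_size)
  tubule <- StagedTubule(
    centerline = cbind(c(0, W - 1), c(cy - 1, cy - 1)),
    stim_center_um = (x0 - 0.5) * px,
    section_um = section_um,
    width_um = 2 * p$radius_um,
    ascending = "+x"
  )
  rois <- partition_rois(tubule, k = k, shape = c(H, W))
  protocol <- StimulusProtocol(onsets = p$onset_s, duration = stim_duration_s,
                               agent = "ATP", concentration = 100)
  pos_excess <- sum(profile[as.character(seq_len(k))])
  neg_excess <- sum(profile[as.character(-seq_len(k))])
  truth <- structure(list(
    profile = profile, tracks = truth_tracks,
    expected_side = if (pos_excess > neg_excess) "+" else if (neg_excess > pos_excess) "-" else "none",
    times = times, params = p
  ), class = "GroundTruth")
  list(recording = rec, rois = rois, protocol = protocol, tubule = tubule,
       truth = truth)
}

#' Hill-model dose-response samples
#'
#' responses = rmax * c^h / (ec50^h + c^h) + Gaussian noise.
#'
#' @param ec50 half-maximal concentration (uM)
#' @param h Hill coefficient
#' @param rmax maximal response
#' @param concentrations tested concentrations (uM); the slice experiments
#'   span 1-1000 uM
#' @param noise_sd response noise SD
#' @param seed RNG seed
#' @return list with `concentrations`, `responses` and `truth`
#' @export
make_dose_response <- function(ec50 = 10, h = 1.5, rmax = 1,
                               concentrations = c(1, 3, 10, 30, 100, 300, 1000),
                               noise_sd = 0, seed = 1L) {
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  mu <- rmax * concentrations^h / (ec50^h + concentrations^h)
  responses <- if (noise_sd > 0) {
    with_seed(seed, mu + stats::rnorm(length(mu), sd = noise_sd))
  } else mu
  truth <- structure(list(ec50 = ec50, h = h, rmax = rmax, mean_response = mu),
                     class = "GroundTruth")
  list(concentrations = concentrations, responses = responses, truth = truth)
}

#' Apply acquisition artifacts to a clean recording
#'
#' Models the three disturbances the preprocessing chain corrects:
#' mains-flicker aliased into per-frame multiplicative gain, constant-
#' velocity stage drift, and spectral bleed of a background channel into a
#' target channel.
#'
#' @param rec [TimeLapseRecording]
#' @param flicker_amplitude relative gain amplitude (0 = none); gains are
#'   1 + a * sin(2 pi f i + phase) with an irrational per-frame frequency,
#'   emulating 50 Hz ripple aliased by a slow frame clock
#' @param drift c(dx, dy) drift velocity (px/frame; 0 = none)
#' @param bleed_alpha fraction of the background channel added into
#'   `target_channel` (requires a "background" channel)
#' @param target_channel channel receiving the bleed
#' @param noise_sd additive Gaussian noise SD
#' @param seed RNG seed (noise and flicker phase)
#' @return list with `recording` (corrupted) and `truth` (gains, drift,
#'   alpha)
#' @export
corrupt <- function(rec, flicker_amplitude = 0, drift = c(0, 0),
                    bleed_alpha = 0, target_channel = "gcamp",
                    noise_sd = 0, seed = 1L) {
  Tn <- n_frames(rec)
  channels <- rec$channels
  gains <- rep(1, Tn)
  truth <- list(gains = gains, drift = drift, alpha = bleed_alpha)
  res <- with_seed(seed, {
    if (flicker_amplitude > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      gains <- 1 + flicker_amplitude * sin(2 * pi * 0.3718 * seq_len(Tn) + phase)
      for (nm in names(channels)) {
        for (i in seq_len(Tn)) channels[[nm]][, , i] <- channels[[nm]][, , i] * gains[i]
      }
    }
    if (bleed_alpha > 0) {
      if (!"background" %in% names(channels)) {
        stop("bleed requires a 'background' channel")
      }
      channels[[target_channel]] <- channels[[target_channel]] +
        bleed_alpha * channels[["background"]]
    }
    if (any(drift != 0)) {
      tt <- seq_len(Tn) - rec$t0_index
      for (nm in names(channels)) {
        for (i in seq_len(Tn)) {
          if (tt[i] == 0) next
          # content moves by +drift*t => resample at p - drift*t
          channels[[nm]][, , i] <- warp_frame(channels[[nm]][, , i],
                                              -drift[1] * tt[i], -drift[2] * tt[i])
        }
      }
    }
    if (noise_sd > 0) {
      for (nm in names(channels)) {
        channels[[nm]] <- pmax(channels[[nm]] +
          array(stats::rnorm(length(channels[[nm]]), sd = noise_sd),
                dim(channels[[nm]])), 0)
      }
    }
    list(channels = channels, gains = gains)
  })
  truth$gains <- res$gains
  list(recording = TimeLapseRecording(res$channels, rec$dt, rec$pixel_size,
                                      rec$t0_index),
       truth = structure(truth, class = "GroundTruth"))
}
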