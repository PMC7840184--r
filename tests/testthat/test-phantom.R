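test_that("phantoms are bit-identical under a fixed seed", {
  p <- phantom_params(n_frames = 8L, noise_sd = 3, seed = 42L)
  a <- make_contracting_tubule(p)
  b <- make_contracting_tubule(p)
  expect_identical(a$recording$channels, b$recording$channels)
  w1 <- make_wave_movie(phantom_params(H = 24L, n_frames = 10L, radius_um = 8,
                                       wall_um = 3, noise_sd = 2, seed = 9),
                        length_um = 120)
  w2 <- make_wave_movie(phantom_params(H = 24L, n_frames = 10L, radius_um = 8,
                                       wall_um = 3, noise_sd = 2, seed = 9),
                        length_um = 120)
  expect_identical(w1$recording$channels, w2$recording$channels)
  # different seeds: identical truth, different noise residuals
  w3 <- make_wave_movie(phantom_params(H = 24L, n_frames = 10L, radius_um = 8,
                                       wall_um = 3, noise_sd = 2, seed = 10),
                        length_um = 120)
  expect_identical(w1$truth$velocity_um_s, w3$truth$velocity_um_s)
  expect_identical(w1$truth$onset_s, w3$truth$onset_s)
  expect_false(identical(w1$recording$channels, w3$recording$channels))
})

test_that("zero amplitude gives identical frames and zero truth field", {
  ph <- make_contracting_tubule(phantom_params(n_frames = 6L, amplitude_um = 0,
                                               ca_amplitude = 0))
  bf <- get_channel(ph$recording, "brightfield")
  for (i in 2:6) expect_identical(bf[, , i], bf[, , 1])
  expect_true(all(ph$truth$displacement$dx == 0))
  expect_true(all(ph$truth$s == 0))
})

test_that("rendered edge displacement matches the truth field", {
  # amplitude 5 um at 1 um/px: outer edge must move inward 5 px (+-0.5 px
  # rasterization tolerance), measured from the rendered masks themselves
  ph <- make_contracting_tubule(phantom_params(n_frames = 40L, amplitude_um = 5,
                                               decay_tau_s = 1e6, rise_tau_s = 1,
                                               onset_s = 5),
                                channels = "brightfield")
  expect_equal(max(ph$truth$edge_displacement_px), 5, tolerance = 0.01)
  bf <- get_channel(ph$recording, "brightfield")
  edge_radius <- function(fr) {
    H <- nrow(fr); cy <- (H + 1) / 2
    row <- fr[round(cy), ]                     # horizontal midline profile
    occ <- which(row > min(row) + 0.25 * diff(range(row)))
    (max(occ) - min(occ)) / 2                  # outer radius estimate (px)
  }
  r0 <- edge_radius(bf[, , 1]); r_end <- edge_radius(bf[, , 40])
  expect_equal(r0 - r_end, 5, tolerance = 0.5)
  expect_equal(max(sqrt(ph$truth$displacement$dx[, , 40]^2 +
                        ph$truth$displacement$dy[, , 40]^2)), 5,
               tolerance = 0.01)
})

test_that("calcium truth leads contraction by exactly the coupling delay", {
  p <- phantom_params(n_frames = 60L, onset_s = 20, coupling_delay_s = 3,
                      rise_tau_s = 1, decay_tau_s = 5)
  ph <- make_contracting_tubule(p)
  t_ca <- ph$truth$times[min(which(ph$truth$ca_trace > 0))]
  t_con <- ph$truth$times[min(which(ph$truth$s > 0))]
  expect_equal(t_con - t_ca, 3)
})

test_that("wave onsets are linear in position by construction", {
  p <- phantom_params(H = 24L, n_frames = 30L, radius_um = 8, wall_um = 3,
                      wave_velocity_um_s = 50, onset_s = 2)
  w <- make_wave_movie(p, length_um = 500)
  tr <- w$truth
  i1 <- 10; i2 <- 200
  expect_equal(tr$onset_s[i2] - tr$onset_s[i1],
               (tr$x_um[i2] - tr$x_um[i1]) / 50)
  # unresolvable flag when onset spread < 2 frames
  fast <- phantom_params(H = 24L, n_frames = 10L, radius_um = 8, wall_um = 3,
                         wave_velocity_um_s = 5000, dt = 1)
  expect_warning(wf <- make_wave_movie(fast, length_um = 200), "unresolvable")
  expect_false(wf$truth$resolvable)
})

test_that("transport truth orders sides correctly", {
  asc <- advection_profile("ascending", k = 2L, v0 = 3)
  expect_true(all(asc[c("1", "2")] > 0) && all(asc[c("-1", "-2")] == 0))
  sym <- advection_profile("symmetric", k = 2L, v0 = 3)
  expect_equal(unname(sym["1"]), unname(sym["-1"]))
  r0 <- advection_profile("roi0", k = 2L, v0 = 3)
  expect_true(r0["0"] > 0 && all(r0[c("-2", "-1", "1", "2")] == 0))
  pp <- phantom_params(H = 32L, n_frames = 10L, radius_um = 10, wall_um = 4,
                       onset_s = 4, seed = 2)
  mv <- make_transport_movie(pp, profile = asc, section_um = 30, n_particles = 20)
  expect_equal(mv$truth$expected_side, "+")
  expect_equal(length(mv$rois), 5)
  expect_equal(mv$protocol$concentration, 100)
  expect_equal(mv$protocol$duration, 10)
})

test_that("corrupt() is identity at zero artifact settings", {
  ph <- make_contracting_tubule(phantom_params(n_frames = 5L))
  out <- corrupt(ph$recording)
  expect_identical(out$recording$channels, ph$recording$channels)
})

test_that("corrupt() drift shows up as the configured global shift", {
  ph <- make_contracting_tubule(phantom_params(n_frames = 11L, amplitude_um = 0),
                                channels = "brightfield")
  out <- corrupt(ph$recording, drift = c(0.5, 0))
  bf <- get_channel(out$recording, "brightfield")
  sh <- tubuliflow:::estimate_global_shift(bf[, , 1], bf[, , 11])
  expect_equal(unname(sh[1]), 5, tolerance = 0.3)   # 0.5 px/frame x 10 frames
  expect_equal(unname(sh[2]), 0, tolerance = 0.2)
})

test_that("dose-response generator hits the defining Hill points", {
  d <- make_dose_response(ec50 = 10, h = 2, rmax = 0.8,
                          concentrations = c(10, 1e9))
  expect_equal(d$responses[1], 0.4)             # c = EC50 -> rmax/2
  expect_equal(d$responses[2], 0.8, tolerance = 1e-6)  # saturation
})
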