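# The estimator is held to an accuracy contract; the full 20-seed sweep
# lives in test-acceptance.R. These are targeted behaviors.

interior <- function(m, margin = 12) {
  m[(margin + 1):(nrow(m) - margin), (margin + 1):(ncol(m) - margin)]
}

test_that("static stack yields a (near) zero field and identical warp", {
  tex <- sin_texture(48, 48, seed = 3)(0, 0)
  stack <- array(rep(tex, 3), c(48, 48, 3))
  field <- estimate_displacement(stack)
  expect_lt(mean(sqrt(field$dx^2 + field$dy^2)), 0.05)
  expect_equal(apply_displacement(stack, DisplacementField(
    array(0, dim(stack)), array(0, dim(stack)))), stack)
})

test_that("constant image warns and returns zero field", {
  stack <- array(5, c(16, 16, 2))
  expect_warning(field <- estimate_displacement(stack), "constant")
  expect_true(all(field$dx == 0) && all(field$dy == 0))
})

test_that("subpixel and multi-pixel rigid shifts are recovered", {
  for (sh in list(c(0.5, 0), c(3, 0), c(-2.5, 1.5))) {
    stack <- shifted_pair_stack(64, 64, sh[1], sh[2], seed = 4)
    field <- estimate_displacement(stack)
    ex <- interior(field$dx[, , 2]); ey <- interior(field$dy[, , 2])
    err <- mean(sqrt((ex - sh[1])^2 + (ey - sh[2])^2))
    tol <- if (max(abs(sh)) <= 0.5) 0.2 else 0.25
    expect_lt(err, tol, label = sprintf("shift (%g,%g) err %.3f", sh[1], sh[2], err))
  }
})

test_that("translation equivariance: common shift leaves relative field unchanged", {
  tex <- sin_texture(64, 64, seed = 5)
  base <- array(c(tex(0, 0), tex(2, 1)), c(64, 64, 2))
  moved <- array(c(tex(1.5, -1), tex(3.5, 0)), c(64, 64, 2))
  f1 <- estimate_displacement(base)
  f2 <- estimate_displacement(moved)
  d1 <- mean(interior(f1$dx[, , 2])); d2 <- mean(interior(f2$dx[, , 2]))
  expect_lt(abs(d1 - d2), 0.1)
})

test_that("integer shift warps back exactly (no interpolation loss)", {
  tex <- sin_texture(32, 32, seed = 6)(0, 0)
  mov <- tubuliflow:::shift_int(tex, 0, 3)    # content moved +3 columns
  stack <- array(c(tex, mov), c(32, 32, 2))
  dx <- array(0, c(32, 32, 2)); dy <- array(0, c(32, 32, 2))
  dx[, , 2] <- 3
  stab <- apply_displacement(stack, DisplacementField(dx, dy))
  # interior must be restored bit-exactly: integer sampling, no blending
  expect_equal(stab[, 1:(32 - 3), 2], tex[, 1:(32 - 3)])
})

test_that("ratiometric pair registration uses one shared field", {
  tex <- sin_texture(64, 64, seed = 7)
  sh <- c(2, -1.5)
  f340 <- array(c(tex(0, 0), tex(sh[1], sh[2])), c(64, 64, 2)) * 0.6
  f380 <- array(c(tex(0, 0), tex(sh[1], sh[2])), c(64, 64, 2))
  out <- register_ratiometric_pair(f340, f380)
  # same field applied to both: stabilized ratio stays flat
  ratio <- out$f340[, , 2] / out$f380[, , 2]
  expect_lt(max(abs(interior(ratio) - 0.6)), 1e-6)
  # both channels restored to t0 geometry: residual shift < 0.25 px
  resid <- tubuliflow:::estimate_global_shift(f380[, , 1], out$f380[, , 2])
  expect_lt(sqrt(sum(resid^2)), 0.25)
  # f340 = f380: field equals single-channel estimate on the doubled image
  fsum <- estimate_displacement(f380 + f380)
  expect_equal(mean(interior(out$field$dx[, , 2])),
               mean(interior(fsum$dx[, , 2])), tolerance = 0.05)
})

test_that("consecutive fields compose to the to_t0 field", {
  tex <- sin_texture(64, 64, seed = 8)
  stack <- array(c(tex(0, 0), tex(1.2, 0.8), tex(2.4, 1.6)), c(64, 64, 3))
  fc <- estimate_displacement(stack, registration_config("consecutive"))
  ft <- compose_to_t0(fc)
  expect_equal(ft$reference_mode, "to_t0")
  expect_equal(mean(interior(ft$dx[, , 3])), 2.4, tolerance = 0.15)
  expect_equal(mean(interior(ft$dy[, , 3])), 1.6, tolerance = 0.15)
})

test_that("drift correction removes the linear component, keeps transients", {
  ph <- make_contracting_tubule(phantom_params(n_frames = 24L, amplitude_um = 4,
                                               onset_s = 10),
                                channels = "brightfield")
  cr <- corrupt(ph$recording, drift = c(0.4, -0.2))
  fixed <- correct_drift(cr$recording, "brightfield")
  expect_equal(unname(fixed$velocity), c(0.4, -0.2), tolerance = 0.08)
  # residual per-frame drift on the corrected recording
  st <- get_channel(fixed$recording, "brightfield")
  resid <- vapply(seq_len(24), function(i) {
    tubuliflow:::estimate_global_shift(st[, , 1], st[, , i])
  }, numeric(2))
  slope <- apply(resid, 1, function(y) coef(lm(y ~ seq_len(24)))[2])
  expect_lt(max(abs(slope)), 0.1)
  # the contraction itself survives: flow strength still peaks near truth
  field <- estimate_displacement(fixed$recording, channel = "brightfield")
  s <- flow_strength(field, ph$truth$wall_mask)
  expect_equal(max(s), max(ph$truth$s), tolerance = 0.15)
  # no-drift input: correction is near identity
  f0 <- correct_drift(ph$recording, "brightfield")
  expect_lt(max(abs(f0$velocity)), 0.05)
})
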