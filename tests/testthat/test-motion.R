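test_that("flow strength matches direct evaluation of the ROI-mean norm", {
  dx <- array(0, c(2, 2, 2)); dy <- array(0, c(2, 2, 2))
  # frame 2 vectors: {(1,0), (0,1), (0,0), (3,4)}
  dx[1, 1, 2] <- 1; dy[2, 1, 2] <- 1; dx[2, 2, 2] <- 3; dy[2, 2, 2] <- 4
  f <- DisplacementField(dx, dy)
  expect_equal(flow_strength(f), c(0, (1 + 1 + 0 + 5) / 4))
  # uniform (3,4) field -> s = 5 for any ROI
  dx[] <- 3; dy[] <- 4
  f2 <- DisplacementField(dx, dy)
  mask <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  expect_equal(flow_strength(f2, mask), c(5, 5))
  expect_error(flow_strength(f2, matrix(FALSE, 2, 2)), "empty")
})

test_that("flow strength is equivariant under joint ROI/field translation", {
  set.seed(41)
  dx <- array(rnorm(12 * 12 * 2), c(12, 12, 2))
  dy <- array(rnorm(12 * 12 * 2), c(12, 12, 2))
  f <- DisplacementField(dx, dy)
  mask <- matrix(FALSE, 12, 12); mask[3:5, 3:5] <- TRUE
  s1 <- flow_strength(f, mask)
  shift <- function(a) { b <- a * 0; b[6:8, 7:9, ] <- a[3:5, 3:5, ]; b }
  mask2 <- matrix(FALSE, 12, 12); mask2[6:8, 7:9] <- TRUE
  s2 <- flow_strength(DisplacementField(shift(dx), shift(dy)), mask2)
  expect_equal(s1, s2)
})

test_that("flow change differencing, smoothing, and telescoping", {
  fs <- flow_change(c(0, 1, 3), smoothing_window = 1L)
  expect_equal(fs$c, c(1, 2))
  # window 1 is bitwise no-op on s
  expect_identical(fs$s_smooth, fs$s)
  # constant s -> c == 0
  expect_equal(flow_change(rep(2, 10), 3L)$c, rep(0, 9))
  # telescoping with window 1: sum(c) = s_k - s_0 exactly
  set.seed(42)
  s <- abs(rnorm(50))
  fs2 <- flow_change(s, 1L)
  expect_equal(sum(fs2$c), s[50] - s[1], tolerance = 1e-14)
  expect_error(flow_change(s, 4L), "odd")
  expect_error(flow_change(c(1, 2), 5L), "exceeds|length")
})

test_that("AUC of a constant over 60 s at 1 Hz is 120, basal window works", {
  times <- 0:200
  series <- rep(2, 201)
  a <- auc_window(series, times, onset_s = 100, window_s = 60)
  expect_equal(a$auc, 120)
  expect_equal(a$auc_basal, 120)
  expect_false(a$truncated)
  z <- auc_window(rep(0, 201), times, 100, 60)
  expect_equal(z$auc, 0)
  expect_warning(tr <- auc_window(series, times, onset_s = 190, window_s = 60),
                 "truncated")
  expect_true(tr$truncated)
  expect_equal(tr$auc, 2 * 10)
  # rectified option
  s2 <- c(rep(-1, 100), rep(1, 101))
  expect_equal(auc_window(s2, times, 100, 60, rectify = TRUE)$auc, 60)
})

test_that("windowed MSE equals brute-force search on small instances", {
  set.seed(43)
  # static stack: zero motion everywhere (tie-break toward zero shift)
  st0 <- array(rep(matrix(runif(18 * 18), 18, 18), 2), c(18, 18, 2))
  m0 <- windowed_mse_motion(st0, sigma = 1, max_distance = 3)
  expect_true(all(m0$maps == 0))
  # global integer shift: interior motion equals the shift norm
  tex <- matrix(runif(28 * 28) * 100, 28, 28)
  st <- array(c(tex, tubuliflow:::shift_int(tex, 0, 2)), c(28, 28, 2))
  m <- windowed_mse_motion(st, sigma = 1, max_distance = 3)
  expect_equal(m$maps[10:19, 10:19, 1], matrix(2, 10, 10))
  # full brute-force equivalence on a random pair (smaller for the oracle)
  a <- matrix(runif(14 * 14) * 50, 14, 14)
  b <- matrix(runif(14 * 14) * 50, 14, 14)
  st2 <- array(c(a, b), c(14, 14, 2))
  fast <- windowed_mse_motion(st2, sigma = 1, max_distance = 2)
  slow <- brute_windowed_mse(a, b, sigma = 1, max_distance = 2)
  expect_equal(fast$maps[, , 1], slow)
  expect_error(windowed_mse_motion(st2, sigma = 1, max_distance = 7), "too large")
})

test_that("contraction detection finds boxcar events and merges gaps", {
  set.seed(44)
  times <- 0:99
  base <- abs(rnorm(100, 0, 0.01))
  s <- base; s[40:49] <- 1          # indices 40..49 are times 39..48
  ev <- detect_contractions(s, times)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_s, 39)
  expect_equal(ev$duration_s, 10)
  expect_equal(ev$peak, 1)
  # flat series: no events
  expect_equal(nrow(detect_contractions(base, times)), 0)
  # events separated by a 1-frame dip merge
  s2 <- base; s2[30:34] <- 1; s2[36:40] <- 1
  ev2 <- detect_contractions(s2, times)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$duration_s, 11)
})

test_that("quantify_motion produces higher post than basal AUC on phantoms", {
  ph <- make_contracting_tubule(phantom_params(H = 48L, W = 48L, n_frames = 26L,
                                               radius_um = 16, wall_um = 6,
                                               amplitude_um = 4, onset_s = 13,
                                               rise_tau_s = 2, decay_tau_s = 4),
                                channels = "brightfield")
  field <- estimate_displacement(ph$recording, channel = "brightfield")
  mr <- quantify_motion(field, ph$truth$wall_mask, frame_times(ph$recording),
                        onset_s = 13, window_s = 11, smoothing_window = 3L)
  expect_gt(mr$auc_post, mr$auc_basal)
  expect_s3_class(mr$flow, "FlowSeries")
})
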