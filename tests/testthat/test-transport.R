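mk_tubule <- function(W = 200, H = 40, section_um = 30, ascending = "increasing") {
  StagedTubule(
    centerline = cbind(c(0, W - 1), c((H - 1) / 2, (H - 1) / 2)),
    stim_center_um = (W - 1) / 2, section_um = section_um, width_um = 24,
    ascending = ascending
  )
}

test_that("partition masks tile the band with no overlaps or gaps", {
  tub <- mk_tubule(W = 240)     # 7 x 30 um sections fit without edge clipping
  rois <- partition_rois(tub, k = 3L, shape = c(40, 240))
  expect_length(rois, 7)
  expect_equal(vapply(rois, function(r) r$index, numeric(1)), -3:3)
  total <- Reduce(`+`, lapply(rois, function(r) r$mask * 1L))
  expect_true(all(total <= 1L))                       # no overlaps
  # union is exactly the covered band: every band pixel in section range
  proj <- tubuliflow:::project_to_polyline(tub$centerline, 40, 240)
  rel <- (proj$s - tub$stim_center_um) / tub$section_um
  band <- proj$d <= 12 & abs(rel) <= 3.5 - 1e-9 &
    proj$s > 1e-9 & proj$s < proj$total - 1e-9
  expect_equal(sum(total), sum(band))                 # no gaps
  # equal arc sections on a straight line -> equal mask sizes
  sizes <- vapply(rois, function(r) sum(r$mask), numeric(1))
  expect_true(diff(range(sizes)) <= 2 * 25)           # 1-px boundary slack
})

test_that("ascending orientation places positive indices correctly", {
  tub_inc <- mk_tubule(ascending = "increasing")
  tub_dec <- mk_tubule(ascending = "decreasing")
  r_inc <- partition_rois(tub_inc, k = 1L, shape = c(40, 200))
  r_dec <- partition_rois(tub_dec, k = 1L, shape = c(40, 200))
  colmean <- function(r) mean(which(r$mask, arr.ind = TRUE)[, 2])
  p1 <- r_inc[[which(vapply(r_inc, function(r) r$index, numeric(1)) == 1)]]
  m1 <- r_dec[[which(vapply(r_dec, function(r) r$index, numeric(1)) == 1)]]
  expect_gt(colmean(p1), 100)       # +1 on the +x side when increasing
  expect_lt(colmean(m1), 100)       # +1 flips side when decreasing
})

test_that("too-short centerlines drop outer ROIs with a warning", {
  tub <- mk_tubule(W = 80, section_um = 30)
  expect_warning(rois <- partition_rois(tub, k = 6L, shape = c(40, 80)),
                 "too short")
  expect_lt(length(rois), 13)
  expect_true(0 %in% vapply(rois, function(r) r$index, numeric(1)))
})

test_that("directionality index has the stated closed forms", {
  prof <- data.frame(roi_index = c(-2, -1, 0, 1, 2),
                     auc = c(2, 3, 10, 3, 2), basal = rep(1, 5))
  expect_equal(directionality_index(prof), 0)             # symmetric
  prof$auc <- c(1, 1, 10, 3, 2)                           # all excess on +
  expect_equal(directionality_index(prof), 1)
  prof$auc <- c(1, 2, 10, 1, 4)                           # A+ = 3, A- = 1
  expect_equal(directionality_index(prof), 0.5)
  prof$auc <- prof$basal                                  # nothing supra-basal
  expect_equal(directionality_index(prof), 0)
  expect_error(directionality_index(data.frame(roi_index = 0:2, auc = 1:3,
                                               basal = 0)), "each side")
})

test_that("reversing the stage direction negates DI exactly", {
  pp <- phantom_params(H = 40L, n_frames = 50L, radius_um = 14, wall_um = 5,
                       onset_s = 23, rise_tau_s = 1.5, decay_tau_s = 6,
                       noise_sd = 2, seed = 5)
  mv <- make_transport_movie(pp, profile = advection_profile("ascending", k = 2L, v0 = 3),
                             section_um = 40, n_particles = 60)
  cfg <- registration_config("consecutive", sigma = 3, iterations = 12,
                             tol = 0.01, global_init = FALSE)
  field <- estimate_displacement(get_channel(mv$recording, "brightfield"), cfg)
  prof_fwd <- transport_profile(mv$recording, mv$rois, mv$protocol,
                                window_s = 20, field = field)
  # same movie, stages read the other way round
  tub_rev <- mv$tubule; tub_rev$ascending <- "decreasing"
  rois_rev <- partition_rois(tub_rev, k = 2L,
                             shape = dim(mv$recording$channels[[1]])[1:2])
  prof_rev <- transport_profile(mv$recording, rois_rev, mv$protocol,
                                window_s = 20, field = field)
  di_f <- directionality_index(prof_fwd)
  di_r <- directionality_index(prof_rev)
  expect_equal(di_r, -di_f, tolerance = 1e-10)
  expect_gt(di_f, 0.5)
})

test_that("advection restricted to ROI 0 leaves neighbors basal", {
  pp <- phantom_params(H = 40L, n_frames = 50L, radius_um = 14, wall_um = 5,
                       onset_s = 23, rise_tau_s = 1.5, decay_tau_s = 6,
                       noise_sd = 2, seed = 6)
  mv <- make_transport_movie(pp, profile = advection_profile("roi0", k = 2L, v0 = 3),
                             section_um = 40, n_particles = 60)
  cfg <- registration_config("consecutive", sigma = 3, iterations = 12,
                             tol = 0.01, global_init = FALSE)
  prof <- transport_profile(mv$recording, mv$rois, mv$protocol, window_s = 20,
                            config = cfg)
  r0 <- prof$auc[prof$roi_index == 0] / prof$basal[prof$roi_index == 0]
  others <- prof$auc[abs(prof$roi_index) == 2] / prof$basal[abs(prof$roi_index) == 2]
  expect_gt(r0, 1.5)
  expect_true(all(others < 1.5))
})
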