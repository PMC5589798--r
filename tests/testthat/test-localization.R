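test_that("blank frames yield no candidates", {
  img <- matrix(10, 32, 32)
  expect_equal(nrow(detect_spots(img, 5)), 0L)
})

test_that("a rendered spot is detected within one pixel and fit to sub-pixel accuracy", {
  det <- data.frame(frame = 0L, x_nm = 10.3 * 107, y_nm = 7.8 * 107)
  stack <- render_frames(det, 24, 24, photons_per_detection = 5000,
                         background = 0, poisson_noise = FALSE)
  img <- stack[, , 1L]
  cands <- detect_spots(img, 5, psf_sigma_px = 1.5)
  expect_equal(nrow(cands), 1L)
  expect_lt(abs(cands$x_px - 10.3), 1)
  expect_lt(abs(cands$y_px - 7.8), 1)
  fit <- fit_gaussian2d(img, cands[1L, ], window_px = 4L)
  expect_true(fit$ok)
  expect_lt(abs(fit$x_px - 10.3), 0.01)
  expect_lt(abs(fit$y_px - 7.8), 0.01)
})

test_that("a flat window is rejected rather than fitted", {
  img <- matrix(100, 15, 15)
  fit <- fit_gaussian2d(img, data.frame(x_px = 7.5, y_px = 7.5), window_px = 3L)
  expect_false(fit$ok)
  expect_match(fit$reason, "flat")
})

test_that("two well-separated spots give two candidates", {
  det <- data.frame(frame = c(0L, 0L),
                    x_nm = c(8 * 107, 8 * 107 + 500), # 500 nm apart
                    y_nm = c(8, 8) * 107)
  stack <- render_frames(det, 24, 24, photons_per_detection = 3000,
                         background = 5, seed = 1)
  cands <- detect_spots(stack[, , 1L], 5)
  expect_equal(nrow(cands), 2L)
})

test_that("localization error scales like the Thompson-style photon limit", {
  true_x <- 11.35; true_y <- 11.6
  errs <- vapply(1:40, function(s) {
    det <- data.frame(frame = 0L, x_nm = true_x * 107, y_nm = true_y * 107)
    stack <- render_frames(det, 24, 24, psf_sigma_nm = 160,
                           photons_per_detection = 1000, background = 2, seed = s)
    cands <- detect_spots(stack[, , 1L], 5)
    if (nrow(cands) == 0L) return(NA_real_)
    fit <- fit_gaussian2d(stack[, , 1L], cands[which.max(cands$value), ], 4L)
    if (!fit$ok) return(NA_real_)
    fit$x_px - true_x
  }, numeric(1))
  expect_gt(mean(!is.na(errs)), 0.9)
  expect_lt(sd(errs, na.rm = TRUE), 3 * (160 / 107) / sqrt(1000))
})

test_that("round trip render -> localize recovers most ground-truth detections", {
  set.seed(9)
  n <- 30
  det <- data.frame(frame = 0:(n - 1L),
                    x_nm = runif(n, 500, 2900), y_nm = runif(n, 500, 2900))
  stack <- render_frames(det, 32, 32, photons_per_detection = 2000,
                         background = 5, seed = 10)
  locs <- localize_stack(stack, threshold_sd = 5)
  matched <- vapply(seq_len(n), function(i) {
    same <- locs[locs$frame == det$frame[i], ]
    nrow(same) > 0 && min(sqrt((same$x_nm - det$x_nm[i])^2 +
                               (same$y_nm - det$y_nm[i])^2)) < 3 * 20
  }, logical(1))
  expect_gte(mean(matched), 0.95)
})

test_that("fiducial identification separates beads from transient emitters", {
  fld <- grid_field(20)
  cfg <- photophysics_config(n_fiducials = 2L, n_frames = 2000L,
                             tau_bleach_frames = 250L)
  sim <- simulate_photophysics(fld, cfg, seed = 11)
  fids <- identify_fiducials(sim$detections, n_frames = 2000L)
  expect_length(fids, 2L)
})

test_that("no persistent emitter means no fiducials and disabled correction", {
  fld <- grid_field(10)
  sim <- simulate_photophysics(fld, photophysics_config(n_frames = 2000L), seed = 12)
  fids <- identify_fiducials(sim$detections, n_frames = 2000L)
  expect_length(fids, 0L)
  expect_message(correct_drift(sim$detections, fids, n_frames = 2000L),
                 "disabled")
})

test_that("linear drift is removed to within 2 nm RMS", {
  fld <- grid_field(40)
  cfg0 <- photophysics_config(n_fiducials = 2L, loc_error_nm = 10)
  cfgd <- photophysics_config(n_fiducials = 2L, loc_error_nm = 10,
                              drift_nm_per_frame = c(0.02, -0.015))
  sim0 <- simulate_photophysics(fld, cfg0, seed = 13)
  simd <- simulate_photophysics(fld, cfgd, seed = 13)
  fids <- identify_fiducials(simd$detections, n_frames = cfgd$n_frames)
  corr <- correct_drift(simd$detections, fids, n_frames = cfgd$n_frames)
  resid <- corr$detections$x_nm - sim0$detections$x_nm
  expect_lt(sqrt(mean(resid^2)), 2)
  # drift correction reduces the spread of a long-lived emitter's detections
  cx <- simd$detections[simd$detections$kind == "complex", ]
  cc <- corr$detections[corr$detections$kind == "complex", ]
  one <- names(which.max(table(cx$fluor_id)))
  expect_lt(var(cc$x_nm[cc$fluor_id == one]), var(cx$x_nm[cx$fluor_id == one]))
})

test_that("zero drift correction is the identity up to fiducial noise", {
  fld <- grid_field(20)
  cfg <- photophysics_config(n_fiducials = 2L, fiducial_error_nm = 0)
  sim <- simulate_photophysics(fld, cfg, seed = 14)
  fids <- identify_fiducials(sim$detections, n_frames = cfg$n_frames)
  corr <- correct_drift(sim$detections, fids, n_frames = cfg$n_frames)
  expect_equal(corr$detections$x_nm, sim$detections$x_nm, tolerance = 1e-10)
  expect_true(all(abs(corr$drift$dx_nm) < 1e-9))
})
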