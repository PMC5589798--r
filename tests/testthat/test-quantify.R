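test_that("the counting equation is the exact quotient", {
  expect_equal(count_molecules(1100, 16, 0.44), 156.25)
  expect_equal(count_molecules(42, 1, 1), 42)
  expect_equal(count_molecules(2 * 1100, 16, 0.44), 2 * 156.25)
})

test_that("subunit copies convert to complexes by the stoichiometry", {
  expect_equal(complexes_from_subunits(250, 3, round_result = TRUE), 83)
  expect_equal(complexes_from_subunits(304, 1), 304)
  expect_equal(complexes_from_subunits(0, 3), 0)
})

test_that("cluster area recovers a known disc geometry", {
  set.seed(41)
  n <- 1500
  r <- sqrt(runif(n)) * 150
  th <- runif(n, 0, 2 * pi)
  det <- data.frame(x_nm = 500 + r * cos(th), y_nm = 500 + r * sin(th))
  a <- cluster_area(det, threshold_per_um2 = 2000)
  expect_equal(as.numeric(a), pi * 0.15^2, tolerance = 0.15)
  # a higher threshold shrinks the measured area
  a_hi <- cluster_area(det, threshold_per_um2 = 10000)
  expect_lt(as.numeric(a_hi), as.numeric(a))
})

test_that("densities are per-cluster quotients", {
  expect_equal(density2d(83, 0.07), 1185.714, tolerance = 1e-6)
  expect_equal(density2d(0, 0.05), 0)
  expect_equal(density2d(10, 0.2), density2d(10, 0.1) / 2)
})

test_that("ICQ hits its limiting values and stays bounded", {
  set.seed(42)
  a <- matrix(runif(64 * 64), 64, 64)
  expect_gt(icq(a, a)$icq, 0.45)                    # B = A
  expect_lt(icq(a, -a + 2)$icq, -0.45)              # B = -A + const
  b <- matrix(runif(64 * 64), 64, 64)
  expect_lt(abs(icq(a, b)$icq), 0.05)               # independence
  # null distribution over seeds: ICQ = 0 +/- 0.02
  nulls <- vapply(1:20, function(s) {
    set.seed(s)
    icq(matrix(runif(4096), 64), matrix(runif(4096), 64))$icq
  }, numeric(1))
  expect_lt(abs(mean(nulls)), 0.02)
  # bounds hold for arbitrary input
  for (s in 1:10) {
    set.seed(s)
    v <- icq(matrix(rnorm(256), 16), matrix(rnorm(256)^2, 16))$icq
    expect_gte(v, -0.5); expect_lte(v, 0.5)
  }
  expect_error(icq(matrix(1, 4, 4), a[1:4, 1:4]), "constant")
})

test_that("integrated intensity is background-corrected and linear", {
  img <- matrix(100, 32, 32)
  cl <- matrix(FALSE, 32, 32); cl[10:20, 10:20] <- TRUE
  bg <- matrix(FALSE, 32, 32); bg[1:5, ] <- TRUE
  expect_equal(integrated_intensity(img, cl, bg), 0)
  # synthetic punctum of known integral on a flat background
  gx <- row(img); gy <- col(img)
  punctum <- 50 * exp(-((gx - 15)^2 + (gy - 15)^2) / (2 * 2^2))
  got <- integrated_intensity(img + punctum, cl, bg)
  expect_equal(got, sum(punctum[cl]), tolerance = 0.02)
  half <- integrated_intensity(img + punctum / 2, cl, bg)
  expect_equal(half, got / 2, tolerance = 0.02)
  expect_error(integrated_intensity(img, cl, matrix(FALSE, 32, 32)), "background")
  expect_error(integrated_intensity(img, cl, cl), "disjoint")
})

test_that("scaffold occupancy follows the beta-subunit arithmetic", {
  expect_equal(occupancy(83, 2, 304), 166 / 304)
  expect_equal(occupancy(0, 2, 304), 0)
  expect_equal(occupancy(40, 2, 304), occupancy(80, 2, 304) / 2)
})

test_that("synapse quantification recovers simulated copy numbers within 10%", {
  # dense ROIs of 80 heteromeric complexes (3 tagged copies each)
  n_syn <- 8
  fld <- simulate_complex_field(
    10, 10, density_um2 = 0.3,
    subunits_per_complex = 5L, tagged_per_complex = 3L,
    synapse_areas_um2 = rep(0.07, n_syn), complexes_per_synapse = 80,
    seed = 43)
  cfg <- photophysics_config(p_det = 0.44, mean_detections_per_burst = 16)
  sim <- simulate_photophysics(fld, cfg, seed = 44)
  det <- sim$detections[sim$detections$kind == "complex", ]
  rois <- data.frame(x_nm = fld$synapses$x_nm, y_nm = fld$synapses$y_nm,
                     radius_nm = fld$synapses$radius_nm + 100)
  clusters <- lapply(seq_len(n_syn), function(s) {
    r <- rois[s, ]
    det[(det$x_nm - r$x_nm)^2 + (det$y_nm - r$y_nm)^2 <= r$radius_nm^2, ]
  })
  q <- quantify_synapses(clusters, n_per_burst = 16, p_det = 0.44,
                         copies_per_complex = 3L, reference_rois = rois)
  expect_equal(nrow(q), n_syn)
  expect_lt(abs(mean(q$N_complexes) - 80) / 80, 0.10)
  # areas in the synaptic range
  expect_true(all(q$area_um2 > 0.01 & q$area_um2 < 0.2))
})

test_that("counting is invariant to corrected drift", {
  fld <- grid_field(60)
  cfg0 <- photophysics_config(n_fiducials = 2L, fiducial_error_nm = 1)
  cfgd <- photophysics_config(n_fiducials = 2L, fiducial_error_nm = 1,
                              drift_nm_per_frame = c(0.03, 0.02))
  sim0 <- simulate_photophysics(fld, cfg0, seed = 45)
  simd <- simulate_photophysics(fld, cfgd, seed = 45)
  fids <- identify_fiducials(simd$detections, n_frames = cfgd$n_frames)
  corr <- correct_drift(simd$detections, fids, n_frames = cfgd$n_frames)
  h0 <- count_bursts(sim0$detections, 250, 120)$histogram
  hd <- count_bursts(corr$detections, 250, 120)$histogram
  expect_identical(as.numeric(h0$counts), as.numeric(hd$counts))
})
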