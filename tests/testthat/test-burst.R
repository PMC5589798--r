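test_that("pointillist rendering conserves detection mass", {
  one <- data.frame(x_nm = 50, y_nm = 50)
  img <- render_pointillist(one, sigma_nm = 10, pixel_nm = 5)
  expect_equal(sum(img) * 25, 1, tolerance = 1e-6)
  hundred <- data.frame(x_nm = runif(100, 40, 60), y_nm = runif(100, 40, 60))
  img2 <- render_pointillist(hundred, 10, 5)
  expect_equal(sum(img2) * 25, 100, tolerance = 1e-6)
  # two coincident detections double the peak exactly
  two <- data.frame(x_nm = c(50, 50), y_nm = c(50, 50))
  expect_equal(max(render_pointillist(two, 10, 5)), 2 * max(img), tolerance = 1e-12)
})

test_that("density filter matches the brute-force pairwise oracle", {
  set.seed(21)
  n <- 400
  det <- data.frame(x_nm = c(runif(n / 2, 0, 2000),
                             rnorm(n / 2, 1000, 10)),
                    y_nm = c(runif(n / 2, 0, 2000),
                             rnorm(n / 2, 1000, 10)))
  det$id <- seq_len(n)
  r <- 50; mn <- 3L
  d <- as.matrix(dist(det[, c("x_nm", "y_nm")]))
  oracle_keep <- vapply(seq_len(n), function(i) sum(d[i, -i] <= r) >= mn, logical(1))
  filt <- density_filter(det, r, mn)
  expect_identical(filt$id, det$id[oracle_keep])
})

test_that("isolated detections are removed, coincident ones kept", {
  det <- data.frame(x_nm = c(0, rep(500, 10)), y_nm = c(0, rep(500, 10)))
  filt <- density_filter(det, 50, 1L)
  expect_equal(nrow(filt), 10L)
})

test_that("cluster selection honors the size and extent thresholds", {
  set.seed(22)
  mk <- function(n, cx, cy, sd = 10) data.frame(
    frame = seq_len(n), x_nm = rnorm(n, cx, sd), y_nm = rnorm(n, cy, sd))
  nine <- mk(9, 500, 500)    # compact, 9 detections -> selected
  eight <- mk(8, 3000, 500)  # below min_detections -> dropped
  det <- rbind(nine, eight)
  cs <- select_clusters(det, det, 100, 9L, 120)
  expect_length(cs$clusters, 1L)
  expect_lt(abs(cs$centroids$x_nm[1L] - 500), 20)
  expect_equal(cs$qc$n_undersize, 1L)
})

test_that("selected clusters match ground-truth complexes", {
  fld <- grid_field(20, tagged = 5L)
  sim <- simulate_photophysics(fld, photophysics_config(p_det = 1,
                                                        loc_error_nm = 10),
                               seed = 23)
  cb <- count_bursts(sim$detections, 250, 120)
  expect_equal(length(cb$clusters$clusters), 20L)
  for (i in seq_len(20)) {
    d <- min(sqrt((fld$complexes$x_nm - cb$clusters$centroids$x_nm[i])^2 +
                  (fld$complexes$y_nm - cb$clusters$centroids$y_nm[i])^2))
    expect_lt(d, 20)
  }
})

test_that("cluster selection is independent of row order", {
  fld <- grid_field(30)
  sim <- simulate_photophysics(fld, photophysics_config(), seed = 24)
  det <- sim$detections
  set.seed(1); perm <- det[sample.int(nrow(det)), ]
  a <- select_clusters(det, det)
  b <- select_clusters(perm, perm)
  oa <- order(a$centroids$x_nm); ob <- order(b$centroids$x_nm)
  expect_equal(a$centroids$x_nm[oa], b$centroids$x_nm[ob])
  expect_equal(a$centroids$n_detections[oa], b$centroids$n_detections[ob])
})

test_that("overlapping masks are discarded and reported", {
  set.seed(25)
  mk <- function(n, cx, cy) data.frame(frame = seq_len(n),
                                       x_nm = rnorm(n, cx, 8),
                                       y_nm = rnorm(n, cy, 8))
  det <- rbind(mk(15, 500, 500), mk(15, 600, 500), mk(15, 2000, 2000))
  cs <- select_clusters(det, det, 100, 9L, 120)
  expect_equal(cs$qc$n_discarded_overlap, 2L)
  expect_length(cs$clusters, 1L)
})

test_that("burst segmentation follows the bleaching-window rule", {
  seg <- segment_bursts(c(10:20, 300:310), 250)
  expect_equal(seg$k, 2L) # gap 280 > 250
  seg2 <- segment_bursts(c(10, 200, 420), 250)
  expect_equal(seg2$k, 1L) # gaps 190, 220 <= 250
  seg3 <- segment_bursts(integer(0), 250)
  expect_equal(seg3$k, 0L)
  expect_equal(nrow(seg3$bursts), 0L)
  # burst bookkeeping: detections conserved, bursts ordered and separated
  expect_equal(sum(seg$bursts$n_detections), 22L)
  expect_true(all(diff(seg$bursts$start_frame) > 250))
})

test_that("burst counts equal the brute-force gap oracle on random traces", {
  set.seed(26)
  for (rep in 1:50) {
    n <- sample(1:40, 1)
    frames <- sort(sample.int(5000, n))
    tau <- sample(c(50, 250, 1200), 1)
    expect_equal(segment_bursts(frames, tau)$k, brute_burst_count(frames, tau))
  }
})

test_that("burst count is invariant under time translation and additive over gaps", {
  set.seed(27)
  frames <- sort(sample.int(3000, 25))
  k0 <- segment_bursts(frames, 250)$k
  expect_equal(segment_bursts(frames + 777, 250)$k, k0)
  other <- sort(sample.int(2000, 15))
  shifted <- other + max(frames) + 251
  expect_equal(segment_bursts(c(frames, shifted), 250)$k,
               k0 + segment_bursts(other, 250)$k)
})

test_that("histogram tallies clusters by burst count", {
  traces <- list(data.frame(frame = c(1, 5)),
                 data.frame(frame = c(10, 11)),
                 data.frame(frame = c(1, 2, 400)))
  h <- build_histogram(traces, 250)
  expect_equal(as.numeric(h$counts), c(2, 1))
  expect_equal(h$n_clusters, 3L)
  expect_equal(h$mean_detections_per_burst, 7 / 4)
})

test_that("p_det = 1 pentamers have modal burst count 5", {
  fld <- grid_field(300, tagged = 5L)
  sim <- simulate_photophysics(fld, photophysics_config(p_det = 1), seed = 28)
  h <- histogram_from_truth(sim)
  expect_equal(unname(which.max(h$counts)), 5L)
})

test_that("simulated burst histograms match the zero-truncated binomial", {
  fld <- grid_field(1000, tagged = 5L)
  sim <- simulate_photophysics(fld, photophysics_config(p_det = 0.44), seed = 29)
  h <- histogram_from_truth(sim)
  expect_lt(abs(h$mean_detections_per_burst - 16), 1)
  # shape consistency at the fitted parameters (two estimated, so dof = k - 2)
  fit <- fit_binomial_free(h, 5)
  p_value <- stats::pchisq(fit$chi2, fit$dof, lower.tail = FALSE)
  expect_gt(p_value, 0.01)
  expect_lt(abs(fit$p_det - 0.44), 0.03)
})
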