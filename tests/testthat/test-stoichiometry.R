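test_that("the binomial pmf is exact and normalized", {
  expect_equal(binomial_pmf(5, 0, 0.44), 0.56^5)
  expect_equal(binomial_pmf(4, 0, 0), 1)
  set.seed(31)
  for (i in 1:5) {
    n <- sample(2:8, 1); p <- runif(1)
    expect_equal(sum(binomial_pmf(n, 0:n, p)), 1)
  }
  expect_error(binomial_pmf(3, 4, 0.5), "binomial_pmf")
  expect_error(binomial_pmf(3, 1, 1.5), "binomial_pmf")
})

test_that("an exact zero-truncated histogram is recovered with chi2 ~ 0", {
  h <- exact_truncated_histogram(5, 0.44, 800)
  fit <- fit_binomial_free(h, 5)
  expect_equal(fit$p_det, 0.44, tolerance = 1e-3)
  expect_equal(fit$N, 800, tolerance = 1e-2)
  expect_lt(fit$chi2, 1e-4)
})

test_that("the zero-burst class closes the accounting exactly", {
  h <- exact_truncated_histogram(5, 0.5, 300)
  fit <- fit_binomial_free(h, 5)
  expect_equal(fit$N - sum(fit$X_k[-1L]), fit$X_k[["0"]], tolerance = 1e-6)
  expect_equal(sum(fit$X_k), fit$N, tolerance = 1e-6)
})

test_that("scaling all frequencies scales N and leaves p_det unchanged", {
  set.seed(32)
  base <- round(500 * dbinom(1:5, 5, 0.47) + runif(5, 0, 5))
  f1 <- fit_binomial_free(burst_histogram(base), 5)
  f3 <- fit_binomial_free(burst_histogram(3 * base), 5)
  expect_equal(f3$p_det, f1$p_det, tolerance = 1e-3)
  expect_equal(f3$N, 3 * f1$N, tolerance = 1e-2)
})

test_that("the optimizer agrees with a fine grid search", {
  set.seed(33)
  for (rep in 1:3) {
    xk <- round(400 * dbinom(1:5, 5, runif(1, 0.35, 0.6)) + runif(5, 0, 8))
    fit <- fit_binomial_free(burst_histogram(xk), 5)
    N_grid <- seq(0.8 * sum(xk), 3 * sum(xk), length.out = 400)
    p_grid <- seq(0.2, 0.8, by = 0.001)
    best <- Inf
    for (p in p_grid) {
      pk <- dbinom(1:5, 5, p)
      # vectorized over N
      chi <- vapply(N_grid, function(N) sum((xk - N * pk)^2 / (N * pk)), numeric(1))
      best <- min(best, min(chi))
    }
    expect_lt(fit$chi2, best + 1e-3)
  }
})

test_that("fixed-p model comparison selects the generating copy number", {
  # exact input: n = 2 wins with chi2 = 0
  h2 <- exact_truncated_histogram(2, 0.44, 400)
  cmp <- fit_binomial_fixed_p(h2, 0.44, 1:5)
  expect_equal(cmp$ranking$n[1L], 2L)
  expect_lt(cmp$ranking$chi2[1L], 1e-6)
  # sampled input from 3 tagged copies
  set.seed(34)
  k <- rbinom(800, 3, 0.44)
  k <- k[k > 0]
  h3 <- burst_histogram(tabulate(k, nbins = max(k)))
  cmp3 <- fit_binomial_fixed_p(h3, 0.44, 1:5)
  expect_equal(cmp3$ranking$n[1L], 3L)
})

test_that("a flat ambiguous histogram is ranked but not accepted", {
  h <- burst_histogram(c(20, 20, 20, 20, 20))
  cmp <- fit_binomial_fixed_p(h, 0.44, 1:5)
  expect_equal(nrow(cmp$ranking), 5L)
  expect_false(any(cmp$ranking$accepted))
})

test_that("chi-square gof follows its definition and band", {
  g <- chi_square_gof(c(10, 20, 30), c(10, 20, 30), 2L)
  expect_equal(g$chi2, 0)
  g1 <- chi_square_gof(c(10 + sqrt(10)), c(10), 0L)
  expect_equal(g1$chi2, 1)
  # calibration: resampling expected counts Poisson gives mean chi2 ~ classes
  set.seed(35)
  Xk <- c(120, 180, 90, 30)
  chis <- replicate(1000, chi_square_gof(rpois(4, Xk), Xk, 0L)$chi2)
  expect_equal(mean(chis), 4, tolerance = 0.1)
})

test_that("zero-expected classes are pooled before summing", {
  g <- chi_square_gof(c(5, 0, 10), c(5, 0, 10), 1L)
  expect_true(g$pooled)
  expect_equal(g$chi2, 0)
  expect_equal(g$n_classes, 2L)
})

test_that("a hexamer fit to trimer data is caught by the plausibility gate", {
  h <- exact_truncated_histogram(3, 0.52, 600)
  fit6 <- fit_binomial_free(h, 6)
  # matching the mean forces p ~ 3 * 0.52 / 6
  expect_lt(fit6$p_det, 0.35)
  gate <- plausibility_gate(fit6)
  expect_false(gate$accepted)
  expect_match(gate$reason, "below")
  fit3 <- fit_binomial_free(h, 3)
  expect_true(plausibility_gate(fit3)$accepted)
  expect_equal(fit3$p_det, 0.52, tolerance = 1e-3)
})

test_that("p_det recovery through the generator is unbiased and tight", {
  # 50 replicates of 1000 pentamers at p_det = 0.44, ground-truth traces
  ps <- vapply(1:50, function(s) {
    fld <- grid_field(1000, tagged = 5L, seed = 1000 + s)
    sim <- simulate_photophysics(fld, photophysics_config(p_det = 0.44),
                                 seed = 2000 + s)
    fit_binomial_free(histogram_from_truth(sim), 5)$p_det
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.44), 0.01)
  expect_lt(sd(ps), 0.02)
})
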