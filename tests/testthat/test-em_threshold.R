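test_that("initial classification labels the top decile as infarct", {
  expect_equal(sum(initialize_labels(1:100)), 10L)
  expect_true(all(which(initialize_labels(1:100)) > 90))
  # ninety zeros and ten fives: interpolated 90th percentile = 0.5
  x <- c(rep(0, 90), rep(5, 10))
  expect_identical(initialize_labels(x), x == 5)
  expect_error(initialize_labels(rep(2, 10)), "degenerate|20")
  expect_error(initialize_labels(rep(2, 30)), "degenerate")
})

test_that("EM recovers the generating parameters of a well-separated mixture", {
  set.seed(42)
  x <- c(rnorm(5000, 0, 1), rnorm(500, 6, 1.5))
  p <- em_fit(x)
  expect_true(p$converged)
  expect_equal(p$mu_n, 0, tolerance = 0.2)
  expect_equal(p$sd_n, 1, tolerance = 0.2)
  expect_equal(p$mu_i, 6, tolerance = 0.2)
  expect_equal(p$sd_i, 1.5, tolerance = 0.2)
  expect_gt(p$threshold, p$mu_n)
  expect_lt(p$threshold, p$mu_i)
})

test_that("component labelling follows the larger mean regardless of orientation", {
  set.seed(8)
  x <- c(rnorm(2000, 10, 1), rnorm(400, 20, 2))
  p <- em_fit(x)
  pm <- em_fit(-x)  # mirrored data: components swap roles
  expect_gt(p$mu_i, p$mu_n)
  expect_gt(pm$mu_i, pm$mu_n)
  expect_equal(pm$mu_i, -p$mu_n, tolerance = 0.1)
  expect_equal(pm$mu_n, -p$mu_i, tolerance = 0.1)
})

test_that("the constrained-EM objective is non-decreasing across iterations", {
  set.seed(21)
  for (k in 1:5) {
    sep <- runif(1, 3, 8)
    x <- c(rnorm(1500, 0, 1), rnorm(round(runif(1, 150, 700)), sep, runif(1, 0.8, 2)))
    p <- em_fit(x)
    expect_true(all(diff(p$objective) > -1e-6 * length(x)))
  }
})

test_that("a single-Gaussian input still yields a valid two-component fit", {
  set.seed(1)
  y <- rnorm(2000, 10, 2)
  p <- em_fit(y)  # constraint forces a split; must not crash
  expect_gt(p$mu_i, p$mu_n)
  expect_gt(p$sd_n, 0)
  expect_gt(p$sd_i, 0)
  expect_gt(p$threshold, p$mu_n)
  expect_lt(p$threshold, p$mu_i)
})

test_that("quantized two-level data (noise-free limit) is fittable", {
  x <- c(rep(20, 300), rep(120, 100))
  p <- em_fit(x)
  expect_equal(p$mu_n, 20, tolerance = 1e-6)
  expect_equal(p$mu_i, 120, tolerance = 1e-6)
  expect_true(p$threshold > 20 && p$threshold < 120)
})

test_that("the fit and threshold are equivariant under affine intensity maps", {
  set.seed(13)
  x <- c(rnorm(1000, 5, 1), rnorm(300, 12, 2))
  p <- em_fit(x)
  for (ab in list(c(2, 10), c(0.3, -4), c(117, 0))) {
    q <- em_fit(ab[1] * x + ab[2])
    expect_equal(q$threshold, ab[1] * p$threshold + ab[2], tolerance = 1e-6)
    expect_equal(q$mu_n, ab[1] * p$mu_n + ab[2], tolerance = 1e-6)
    expect_equal(q$sd_i, ab[1] * p$sd_i, tolerance = 1e-6)
  }
})

test_that("the symmetric equal-variance threshold is the midpoint", {
  pair <- make_pair(0, 1, 10, 1, 0.5)
  expect_equal(optimal_threshold(pair), 5)
})

test_that("the threshold matches a fine grid search of the posterior-equality point", {
  set.seed(99)
  for (k in 1:20) {
    pair <- draw_valid_pair()
    t_grid <- threshold_grid_oracle(pair)
    expect_equal(optimal_threshold(pair), t_grid, tolerance = 1e-3)
  }
})

test_that("the threshold rises as the infarct mixing weight shrinks", {
  ts <- vapply(c(0.3, 0.1, 0.01),
               function(p) optimal_threshold(make_pair(0, 1, 6, 2, p)),
               numeric(1))
  expect_true(all(diff(ts) > 0))
})

test_that("the threshold is bracketed by the means for well-separated pairs", {
  set.seed(5)
  for (k in 1:20) {
    sd_n <- runif(1, 0.3, 1.5); sd_i <- runif(1, 0.3, 2)
    mu_i <- sd_n + sd_i + runif(1, 0.5, 5)  # |mu_i - mu_n| > sd_n + sd_i
    pair <- make_pair(0, sd_n, mu_i, sd_i, runif(1, 0.1, 0.9))
    t <- optimal_threshold(pair)
    expect_gt(t, 0)
    expect_lt(t, mu_i)
  }
})

test_that("the unweighted threshold variant ignores the mixing weights", {
  pair <- make_pair(0, 1, 10, 1, 0.1)
  expect_equal(optimal_threshold(pair, weighted = FALSE), 5)
  expect_gt(optimal_threshold(pair, weighted = TRUE), 5)
})
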