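test_that("n-SD thresholds flag the theoretical Gaussian tails on pure noise", {
  set.seed(55)
  n <- 40
  myo <- array(TRUE, c(n, n, 40))
  img <- image_stack(array(stats::rnorm(n * n * 40, 50, 8), dim(myo)), 1, 1)
  remote <- myo
  r2 <- threshold_nsd(img, myo, remote, 2)
  r3 <- threshold_nsd(img, myo, remote, 3)
  expect_equal(r2$pct_lvm, 100 * stats::pnorm(-2), tolerance = 0.1)
  expect_equal(r3$pct_lvm, 100 * stats::pnorm(-3), tolerance = 0.3)
  expect_error(threshold_nsd(image_stack(array(1, c(4, 4, 1)), 1, 1),
                             array(TRUE, c(4, 4, 1)), array(TRUE, c(4, 4, 1)),
                             2),
               "zero spread")
})

test_that("n-SD masks are nested: 5SD within 3SD within 2SD", {
  ph <- generate_phantom(phantom_spec(seed = 61))
  asn <- assign_sectors(ph$seg, ph$insertions)
  rem <- remote_mask(ph$seg, asn, load_extent_models()$LAD)
  myo <- ph$seg$myocardium_mask
  m2 <- threshold_nsd(ph$stack, myo, rem, 2)$mask
  m3 <- threshold_nsd(ph$stack, myo, rem, 3)$mask
  m5 <- threshold_nsd(ph$stack, myo, rem, 5)$mask
  expect_true(all(which(m5) %in% which(m3)))
  expect_true(all(which(m3) %in% which(m2)))
})

test_that("FWHM-min thresholds at half of the myocardial range and is affine invariant", {
  d <- c(5, 5, 1)
  myo <- array(TRUE, d)
  I <- array(seq(0, 100, length.out = 25), d)
  r <- threshold_fwhm_min(image_stack(I, 1, 1), myo)
  expect_equal(r$threshold, 50)
  r2 <- threshold_fwhm_min(image_stack(2 * I + 30, 1, 1), myo)
  expect_identical(r$mask, r2$mask)
  expect_error(threshold_fwhm_min(image_stack(array(3, d), 1, 1), myo),
               "constant")
})

test_that("FWHM-min equals a grid-search half-max oracle on a bimodal phantom", {
  ph <- generate_phantom(phantom_spec(seed = 37, mode = "PSIR"))
  myo <- ph$seg$myocardium_mask
  r <- threshold_fwhm_min(ph$stack, myo)
  x <- ph$stack$intensities[myo]
  # oracle: smallest grid value whose exceedance set equals the half-max cut
  t_oracle <- min(x) + 0.5 * (max(x) - min(x))
  expect_equal(sum(r$mask), sum(x > t_oracle))
})

test_that("FWHM-remote anchors at the remote mean and warns on IR input", {
  d <- c(5, 5, 1)
  myo <- array(TRUE, d)
  I <- array(seq(0, 100, length.out = 25), d)
  remote <- array(FALSE, d); remote[I < 10] <- TRUE
  img_ps <- image_stack(I, 1, 1, mode = "PSIR")
  mu_r <- mean(I[remote])
  r <- threshold_fwhm_remote(img_ps, myo, remote)
  expect_equal(r$threshold, mu_r + 0.5 * (100 - mu_r))
  expect_warning(threshold_fwhm_remote(image_stack(I, 1, 1, mode = "IR"),
                                       myo, remote),
                 "PSIR")
  flat <- image_stack(array(7, d), 1, 1, mode = "PSIR")
  expect_error(threshold_fwhm_remote(flat, myo, myo), "does not exceed")
})

test_that("Otsu separates two tight clusters and matches EBImage's implementation", {
  d <- c(10, 10, 1)
  myo <- array(TRUE, d)
  set.seed(3)
  x <- c(stats::rnorm(70, 0, 0.5), stats::rnorm(30, 100, 0.5))
  img <- image_stack(array(x, d), 1, 1)
  r <- threshold_otsu(img, myo)
  expect_gt(r$threshold, 5); expect_lt(r$threshold, 95)
  expect_equal(sum(r$mask), 30)
  # exhaustive-search oracle: the returned cut maximizes the between-class
  # variance over every possible threshold between sorted sample values
  bcv_at <- function(t) {
    a <- x[x <= t]; b <- x[x > t]
    if (!length(a) || !length(b)) return(0)
    length(a) / length(x) * length(b) / length(x) * (mean(a) - mean(b))^2
  }
  cand <- (sort(x)[-1] + sort(x)[-length(x)]) / 2
  expect_equal(bcv_at(r$threshold), max(vapply(cand, bcv_at, numeric(1))),
               tolerance = 1e-6)
  # independent implementation: EBImage::otsu on the normalized histogram
  xn <- (x - min(x)) / (max(x) - min(x))
  t_eb <- EBImage::otsu(EBImage::Image(matrix(xn, 10, 10)),
                        range = c(0, 1), levels = 256L)
  t_mine <- (r$threshold - min(x)) / (max(x) - min(x))
  expect_equal(t_mine, t_eb, tolerance = 2 / 256)
  expect_error(threshold_otsu(image_stack(array(5, d), 1, 1), myo),
               "distinct")
})

test_that("Otsu flags low separation on unimodal input", {
  d <- c(12, 12, 1)
  myo <- array(TRUE, d)
  set.seed(9)
  uni <- image_stack(array(stats::rnorm(144, 50, 3), d), 1, 1)
  expect_true(threshold_otsu(uni, myo)$low_separation)
  bim <- image_stack(array(c(stats::rnorm(100, 0, 1), stats::rnorm(44, 60, 1)), d), 1, 1)
  expect_false(threshold_otsu(bim, myo)$low_separation)
})

test_that("the plain EM comparator equals the EWA core before steps 3-6", {
  ph <- generate_phantom(phantom_spec(seed = 49))
  myo <- ph$seg$myocardium_mask
  r <- threshold_em_pure(ph$stack, myo)
  expect_identical(r$mask, myo & ph$stack$intensities > r$threshold)
  # cross-check against the pipeline's own threshold and alpha = 0 core
  pair <- em_fit(ph$stack$intensities[myo])
  core0 <- segment_core(build_speed(ph$stack, myo, pair$threshold), alpha = 0)
  expect_identical(r$mask, core0)
  # pure-noise myocardium still yields a non-empty comparator mask
  set.seed(2)
  noise <- image_stack(array(stats::rnorm(prod(dim(myo)), 30, 5), dim(myo)), 1, 1)
  expect_gt(sum(threshold_em_pure(noise, myo)$mask), 0)
})
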