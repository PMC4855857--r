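test_that("image_stack validates geometry and intensities", {
  arr <- array(1, c(4, 4, 2))
  img <- image_stack(arr, 1.5, 8)
  expect_equal(voxel_volume(img), 1.5^2 * 8)
  expect_equal(voxel_volume(image_stack(arr, 1.5, 8, slice_gap = 2)),
               1.5^2 * 10)
  expect_equal(voxel_volume(image_stack(array(1, c(2, 2, 1)), 1, 1)), 1)
  expect_error(image_stack(arr, 0, 8), "pixel_spacing")
  expect_error(image_stack(arr, 1.5, -1), "slice_thickness")
  bad <- arr; bad[1] <- NA
  expect_error(image_stack(bad, 1.5, 8), "finite")
})

test_that("concentric-circle rasterization matches the annulus area and a brute-force oracle", {
  # generic (non-integer) center so no pixel center sits exactly on an edge
  epi <- circle_poly(32.3, 31.7, 10)
  endo <- circle_poly(32.3, 31.7, 5)
  m <- rasterize_contours(endo, epi, c(64, 64))
  expect_equal(sum(m), pi * (10^2 - 5^2), tolerance = 0.02)
  # exact pixelwise agreement with the independent ray-casting oracle
  px <- rep(seq_len(64), each = 64); py <- rep(seq_len(64), times = 64)
  in_epi <- pip_oracle(px, py, epi, on_boundary = TRUE)
  in_endo <- pip_oracle(px, py, endo, on_boundary = FALSE)
  expect_identical(as.vector(m), in_epi & !in_endo)
})

test_that("integer-aligned square contours give an exact frame of pixels", {
  epi <- cbind(c(2, 8, 8, 2), c(2, 2, 8, 8))
  endo <- cbind(c(4, 6, 6, 4), c(4, 4, 6, 6))
  m <- rasterize_contours(endo, epi, c(10, 10))
  # inside-or-on epi: centers 2..8 (49 px); strictly inside endo: (5,5) only
  expect_equal(sum(m), 49 - 1)
  expect_false(m[5, 5])
  expect_true(m[4, 4])   # on the endo boundary counts as myocardium
  expect_true(m[2, 5])   # on the epi boundary counts as myocardium
})

test_that("rasterization rejects degenerate geometry", {
  sq <- cbind(c(2, 8, 8, 2), c(2, 2, 8, 8))
  expect_error(rasterize_contours(sq, sq, c(10, 10)), "coincide")
  expect_error(rasterize_contours(cbind(c(1, 2), c(1, 2)), sq, c(10, 10)),
               "3 vertices")
  big <- cbind(c(1, 9, 9, 1), c(1, 1, 9, 9))
  expect_error(rasterize_contours(big, sq, c(10, 10)), "not strictly inside")
})

test_that("myocardial volume is count times voxel volume and additive over disjoint masks", {
  epi <- circle_poly(16, 16, 10); endo <- circle_poly(16, 16, 5)
  seg <- lv_segmentation(rep(list(list(endo = endo, epi = epi)), 2), c(32, 32))
  geom <- image_stack(array(0, c(32, 32, 2)), 1.5, 8)
  expect_equal(myocardial_volume(seg, geom),
               sum(seg$myocardium_mask) * 1.5^2 * 8)
  # additivity: the two slices partition the mask
  v1 <- sum(seg$myocardium_mask[, , 1]) * voxel_volume(geom)
  v2 <- sum(seg$myocardium_mask[, , 2]) * voxel_volume(geom)
  expect_equal(myocardial_volume(seg, geom), v1 + v2)
  expect_error(lv_segmentation(list(NULL), c(8, 8)), "zero")
})

test_that("contours survive a JSON round trip", {
  ph <- generate_phantom(phantom_spec(n_slices = 3, seed = 11))
  path <- tempfile(fileext = ".json")
  write_contours(ph$seg$contours, path)
  back <- read_contours(path)
  expect_equal(length(back), 3L)
  expect_equal(back[[2]]$endo, unname(ph$seg$contours[[2]]$endo))
  expect_equal(back[[3]]$epi, unname(ph$seg$contours[[3]]$epi))
})

test_that("label_components separates diagonal voxels under 4- but not 8-connectivity", {
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(max(label_components(m, 4L)), 2L)
  expect_equal(max(label_components(m, 8L)), 1L)
  a <- array(FALSE, c(3, 3, 3)); a[1, 1, 1] <- TRUE; a[2, 2, 2] <- TRUE
  expect_equal(max(label_components(a, 6L)), 2L)
  expect_equal(max(label_components(a, 26L)), 1L)
})
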