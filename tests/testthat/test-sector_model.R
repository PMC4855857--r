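# Geometry convention in these fixtures: image x right, y down; the
# anterior RV insertion sits up-left (angle 225 deg) and the inferior
# insertion down-left (135 deg), so the septum spans the left of the image
# and carries sector indices 1-6.

make_ins <- function(n = 33) {
  c0 <- (n + 1) / 2
  insertion_points(
    c(c0 + 14 * cos(225 * pi / 180), c0 + 14 * sin(225 * pi / 180)),
    c(c0 + 14 * cos(135 * pi / 180), c0 + 14 * sin(135 * pi / 180)))
}

test_that("voxels at bin-center angles fill each (ring, sector) exactly once", {
  n <- 33; c0 <- (n + 1) / 2
  myo <- array(FALSE, c(n, n, 9))
  # one voxel per 15-degree bin center, at radius 10, on every slice
  ang <- 225 - (seq_len(24) - 0.5) * 15  # direction: decreasing theta
  for (s in 1:9) for (a in ang) {
    myo[round(c0 + 10 * sin(a * pi / 180)), round(c0 + 10 * cos(a * pi / 180)), s] <- TRUE
  }
  seg <- seg_from_masks(myo, centers = matrix(rep(c0, 18), 9, 2))
  asn <- assign_sectors(seg, make_ins(n))
  tab <- table(ring = asn$ring[myo], sector = asn$sector[myo])
  expect_equal(dim(tab), c(9L, 24L))
  expect_true(all(tab == 1L))
})

test_that("a voxel at the anterior insertion angle lands in sector 1 (half-open bins)", {
  n <- 33; c0 <- (n + 1) / 2
  myo <- array(FALSE, c(n, n, 1))
  r <- 8 / sqrt(2)
  myo[round(c0 - r), round(c0 - r), 1] <- TRUE  # exactly at 225 deg
  seg <- seg_from_masks(myo, centers = matrix(c0, 1, 2))
  asn <- assign_sectors(seg, make_ins(n))
  expect_equal(asn$sector[myo], 1L)
})

test_that("slice-to-ring mapping is the documented proportional midpoint rule", {
  # ring(s) = floor((s - 0.5) * 9 / S) + 1
  n <- 17
  mk <- function(S) {
    myo <- array(FALSE, c(n, n, S)); myo[5, 5, ] <- TRUE
    asn <- assign_sectors(seg_from_masks(myo, centers = matrix(9, S, 2)),
                          make_ins(n))
    vapply(seq_len(S), function(s) asn$ring[5, 5, s], integer(1))
  }
  expect_equal(mk(9L), 1:9)
  expect_equal(mk(6L), c(1L, 3L, 4L, 6L, 7L, 9L))  # every slice mapped
  expect_equal(mk(3L), c(2L, 5L, 8L))
  expect_equal(mk(12L), c(1L, 2L, 2L, 3L, 4L, 5L, 5L, 6L, 7L, 8L, 8L, 9L))
})

test_that("sector assignment is equivariant under a 90-degree rotation", {
  ph <- generate_phantom(phantom_spec(n_slices = 2, seed = 4))
  seg <- ph$seg
  asn <- assign_sectors(seg, ph$insertions)
  n <- dim(seg$myocardium_mask)[1]
  # rotate 90 deg clockwise: point (x, y) -> (n + 1 - y, x)
  rot_mask <- function(m) aperm(m[n:1, , , drop = FALSE], c(2, 1, 3))
  rot_pt <- function(p) c(n + 1 - p[2], p[1])
  seg_r <- seg_from_masks(rot_mask(seg$myocardium_mask),
                          centers = t(apply(seg$lv_center, 1, rot_pt)))
  ins_r <- insertion_points(rot_pt(ph$insertions$anterior),
                            rot_pt(ph$insertions$inferior))
  asn_r <- assign_sectors(seg_r, ins_r)
  expect_identical(rot_mask(asn$sector), asn_r$sector)
  expect_identical(rot_mask(asn$ring), asn_r$ring)
})

test_that("remote and territory masks partition the myocardium", {
  ph <- generate_phantom(phantom_spec(seed = 6))
  asn <- assign_sectors(ph$seg, ph$insertions)
  models <- load_extent_models()
  for (a in c("LAD", "RCA", "LCx", "LM")) {
    rem <- remote_mask(ph$seg, asn, models[[a]])
    terr <- ph$seg$myocardium_mask & !rem
    expect_true(all((rem | terr) == ph$seg$myocardium_mask))
    expect_false(any(rem & terr))
  }
  # LM is the union of territories, so its remote is the smallest
  rem_lm <- remote_mask(ph$seg, asn, models$LM)
  rem_lad <- remote_mask(ph$seg, asn, models$LAD)
  expect_true(all(which(rem_lm) %in% which(rem_lad)))
})

test_that("a half-circumference model leaves the complementary half as remote", {
  n <- 33; c0 <- (n + 1) / 2
  myo <- array(annulus_mask(n, 6, 12), c(n, n, 9))
  seg <- seg_from_masks(myo, centers = matrix(c0, 9, 2))
  asn <- assign_sectors(seg, make_ins(n))
  model <- max_extent_model("LAD", outer(rep(TRUE, 9), 1:24 <= 12))
  rem <- remote_mask(seg, asn, model)
  expect_equal(sum(rem) / sum(myo), 0.5, tolerance = 0.05)
  expect_true(all((asn$sector[rem]) >= 13))
  # a model covering everything leaves no remote
  full <- max_extent_model("LAD", matrix(TRUE, 9, 24))
  expect_error(remote_mask(seg, asn, full), "degenerate")
})

test_that("coincident insertion points are rejected", {
  expect_error(insertion_points(c(3, 3), c(3, 3)), "coincide")
})

test_that("extent-model configs load, validate and round-trip", {
  models <- load_extent_models()
  expect_named(models, c("LAD", "LCx", "RCA", "LM"))
  expect_identical(models$LM$included,
                   models$LAD$included | models$LCx$included |
                     models$RCA$included)
  path <- tempfile(fileext = ".yaml")
  save_extent_models(models, path)
  back <- load_extent_models(path)
  for (a in names(models))
    expect_identical(back[[a]]$included, models[[a]]$included)
  # missing artery is an error
  cfg <- yaml::read_yaml(path)
  cfg$RCA <- NULL
  path2 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path2)
  expect_error(load_extent_models(path2), "RCA")
  # out-of-range sector is an error
  cfg2 <- yaml::read_yaml(path)
  cfg2$LAD[[1]] <- c(1L, 99L)
  yaml::write_yaml(cfg2, path2)
  expect_error(load_extent_models(path2), "out of range")
})
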