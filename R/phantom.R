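# Synthetic LGE phantom with voxel-level ground truth.  The phantom
# emulates a short-axis LGE acquisition: an annular myocardium over a slice
# stack with nulled (near-zero in IR) remote myocardium, a hyperenhanced
# transmural wedge of infarct whose edges carry a continuous infarct
# fraction (partial volume, modelled as Gaussian blur of the fraction map
# before noise), an optional hypointense MVO core, bright LV blood pool, an
# optional multiplicative second-order coil-intensity gradient, and
# Gaussian noise with magnitude folding in IR mode.

#' Phantom specification
#'
#' Defaults mirror a typical short-axis LGE acquisition: 1.5 x 1.5 x 8.0 mm
#' voxels, 9 gapless slices, endo/epi radii 24/33 mm.  Contrast defaults
#' (remote mean 20, infarct mean 120, noise SD 10) give a
#' contrast-to-noise ratio of 10 between infarct and nulled remote
#' myocardium.  The coil field defaults to flat (no gradient).
#'
#' @param grid in-plane grid size (pixels, square).
#' @param n_slices number of slices (slice 1 basal).
#' @param pixel_spacing,slice_thickness,slice_gap voxel geometry in mm.
#' @param endo_radius,epi_radius endo/epicardial radii in mm.
#' @param infarct_span angular span of the infarct wedge in degrees.
#' @param infarct_center_angle wedge center angle in degrees
#'   (image convention: x right, y down; 270 = anterior wall at the image top).
#' @param transmurality fraction of wall thickness infarcted, in (0, 1].
#' @param infarct_slices slice indices carrying infarct (default: all).
#' @param mvo include a microvascular-obstruction core.
#' @param remote_mean,infarct_mean,blood_mean,background_mean tissue
#'   intensities (arbitrary units).
#' @param noise_sd Gaussian noise SD.
#' @param blur_sd partial-volume point-spread SD in mm.
#' @param coil optional length-6 coefficients (1, x, y, x^2, xy, y^2) of a
#'   multiplicative field on normalized in-plane coordinates; `NULL` = flat.
#' @param mode acquisition mode (`"IR"` folds magnitudes, `"PSIR"`/`"T1w"`
#'   keep signed values).
#' @param seed integer seed; a fixed seed makes the phantom bit-identical.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = 64L, n_slices = 9L,
                         pixel_spacing = 1.5, slice_thickness = 8,
                         slice_gap = 0,
                         endo_radius = 24, epi_radius = 33,
                         infarct_span = 90, infarct_center_angle = 270,
                         transmurality = 1, infarct_slices = NULL,
                         mvo = FALSE,
                         remote_mean = 20, infarct_mean = 120,
                         blood_mean = 150, background_mean = 5,
                         noise_sd = 10, blur_sd = 1.5,
                         coil = NULL,
                         mode = c("IR", "PSIR", "T1w"), seed = 1L) {
  mode <- match.arg(mode)
  if (infarct_mean <= remote_mean) stop("infarct mean must exceed remote mean")
  if (noise_sd < 0) stop("noise SD must be >= 0")
  if (!(transmurality > 0 && transmurality <= 1))
    stop("transmurality must lie in (0, 1]")
  if (epi_radius <= endo_radius) stop("epicardial radius must exceed endocardial")
  if (epi_radius / pixel_spacing >= grid / 2 - 1)
    stop("epicardial radius does not fit the grid")
  infarct_slices <- infarct_slices %||% seq_len(n_slices)
  if (any(infarct_slices < 1L | infarct_slices > n_slices))
    stop("spec error: infarct wedge outside the slice stack")
  if (!is.null(coil) && length(coil) != 6L)
    stop("coil must be NULL or 6 polynomial coefficients")
  structure(as.list(environment()), class = "phantom_spec")
}

# 1D Gaussian convolution with reflected boundaries (mass-conserving).
#' @noRd
conv1d_reflect <- function(v, kern) {
  r <- (length(kern) - 1L) %/% 2L
  n <- length(v)
  pad <- c(v[r:1], v, v[n:(n - r + 1L)])
  out <- stats::filter(pad, kern, sides = 2)
  as.numeric(out[(r + 1L):(r + n)])
}

# Separable 2D Gaussian blur of a matrix, reflected boundaries.
#' @noRd
blur2d <- function(m, sd_px) {
  if (sd_px <= 0) return(m)
  r <- max(1L, ceiling(3 * sd_px))
  k <- stats::dnorm(-r:r, sd = sd_px)
  k <- k / sum(k)
  m <- apply(m, 2, conv1d_reflect, kern = k)
  t(apply(t(m), 2, conv1d_reflect, kern = k))
}

# Signed angular distance in degrees, in (-180, 180].
#' @noRd
ang_diff <- function(a, b) ((a - b + 180) %% 360) - 180

#' Generate a synthetic LGE phantom
#'
#' Builds the continuous infarct-fraction map (a wedge of the requested
#' span and transmurality inside the annulus, rasterized at pixel centers
#' and convolved with the Gaussian PSF -- the blur is what produces the
#' continuous partial-volume fractions at the wedge edges), composes
#' intensities
#' (`remote + fraction * (infarct - remote)` over the myocardium, bright
#' blood pool, dim background), carves the optional MVO core down to the
#' remote intensity, applies the multiplicative coil field, and adds
#' Gaussian noise; IR mode takes the magnitude so the nulled remote
#' exhibits folded noise.  The returned truth carries the post-blur,
#' pre-noise fraction map; MVO voxels are fully infarcted tissue, so
#' carving affects intensity only, never the truth.
#'
#' @param spec [phantom_spec]
#' @return list with `stack` ([image_stack]), `seg` ([lv_segmentation]),
#'   `insertions` ([insertion_points]), and `truth` (fields `fraction`,
#'   `true_pct_lvm`, `mvo_mask`, `contours`).
#' @export
generate_phantom <- function(spec) {
  base <- phantom_noiseless(spec)
  finalize_phantom(base, spec$mode, spec$seed, spec$noise_sd)
}

# Deterministic pre-noise phantom (shared by generate_phantom and
# generate_paired).
#' @noRd
phantom_noiseless <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid; ns <- spec$n_slices; ps <- spec$pixel_spacing
  c0 <- (n + 1) / 2
  re <- spec$endo_radius / ps
  rp <- spec$epi_radius / ps
  r_out <- re + spec$transmurality * (rp - re)

  theta <- seq(0, 2 * pi, length.out = 97L)[-97L]
  circ <- function(r) cbind(c0 + r * cos(theta), c0 + r * sin(theta))
  contours <- rep(list(list(endo = circ(re), epi = circ(rp))), ns)
  seg <- lv_segmentation(contours, c(n, n))

  # infarct indicator at pixel centers (x = col, y = row, column-major);
  # the PSF blur below turns it into the continuous partial-volume fraction
  px <- rep(seq_len(n), each = n)
  py <- rep(seq_len(n), times = n)
  dx <- px - c0; dy <- py - c0
  rr <- sqrt(dx^2 + dy^2)
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  hit <- rr >= re & rr <= r_out &
    abs(ang_diff(ang, spec$infarct_center_angle)) <= spec$infarct_span / 2
  frac2d <- blur2d(matrix(as.numeric(hit), n, n), spec$blur_sd / ps)

  fraction <- array(0, c(n, n, ns))
  for (s in spec$infarct_slices) fraction[, , s] <- frac2d

  # MVO core: sub-wedge hugging the endocardium on the middle infarct slices
  mvo_mask <- array(FALSE, c(n, n, ns))
  if (isTRUE(spec$mvo)) {
    w <- r_out - re
    m2d <- matrix(rr >= re & rr <= re + 0.4 * w &
                    abs(ang_diff(ang, spec$infarct_center_angle)) <=
                      spec$infarct_span / 4, n, n)
    isl <- spec$infarct_slices
    mid <- isl[seq(max(1L, floor(length(isl) / 3) + 1L),
                   min(length(isl), ceiling(2 * length(isl) / 3)))]
    for (s in mid) mvo_mask[, , s] <- m2d & seg$myocardium_mask[, , s]
  }

  myo <- seg$myocardium_mask
  img <- array(spec$background_mean, c(n, n, ns))
  img[seg$blood_mask] <- spec$blood_mean
  img[myo] <- spec$remote_mean +
    fraction[myo] * (spec$infarct_mean - spec$remote_mean)
  img[mvo_mask] <- spec$remote_mean

  if (!is.null(spec$coil)) {
    xn <- (px - c0) / (n / 2); yn <- (py - c0) / (n / 2)
    fld <- matrix(cbind(1, xn, yn, xn^2, xn * yn, yn^2) %*% spec$coil, n, n)
    if (any(fld <= 0)) stop("coil field must be strictly positive")
    for (s in seq_len(ns)) img[, , s] <- img[, , s] * fld
  }

  true_pct <- 100 * sum(fraction[myo]) / sum(myo)
  ant <- c(c0 + (rp + 3) * cos(225 * pi / 180), c0 + (rp + 3) * sin(225 * pi / 180))
  inf <- c(c0 + (rp + 3) * cos(135 * pi / 180), c0 + (rp + 3) * sin(135 * pi / 180))
  list(img = img, seg = seg,
       insertions = insertion_points(ant, inf),
       truth = list(fraction = fraction, true_pct_lvm = true_pct,
                    mvo_mask = mvo_mask, contours = contours),
       spec = spec)
}

#' @noRd
finalize_phantom <- function(base, mode, seed, noise_sd) {
  spec <- base$spec
  img <- base$img
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    img <- img + stats::rnorm(length(img), 0, noise_sd)
  }
  if (mode == "IR") img <- abs(img)
  stack <- image_stack(img, pixel_spacing = spec$pixel_spacing,
                       slice_thickness = spec$slice_thickness,
                       slice_gap = spec$slice_gap, mode = mode)
  list(stack = stack, seg = base$seg, insertions = base$insertions,
       truth = base$truth)
}

#' Generate paired IR and PSIR phantoms sharing one ground truth
#'
#' Emulates a paired IR/PSIR acquisition of the same heart: identical
#' geometry, contours and truth; mode-specific noise models (IR magnitude
#' folding vs signed PSIR) with independent noise draws from sub-seeds
#' derived from `spec$seed`.
#'
#' @param spec [phantom_spec]
#' @return list with `ir`, `psir` (each as returned by [generate_phantom])
#'   and the shared `truth`.
#' @export
generate_paired <- function(spec) {
  base <- phantom_noiseless(spec)
  s1 <- as.integer((as.numeric(spec$seed) * 2654435 + 101) %% 2147483647)
  s2 <- as.integer((as.numeric(spec$seed) * 2654435 + 202) %% 2147483647)
  ir <- finalize_phantom(base, "IR", s1, spec$noise_sd)
  psir <- finalize_phantom(base, "PSIR", s2, spec$noise_sd)
  list(ir = ir, psir = psir, truth = base$truth)
}
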