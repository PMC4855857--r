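# Step 3: grow the infarct core from supra-threshold seeds with a discrete
# narrow-band level set.  The driving force (speed) is a linear function of
# intensity: zero at the EM threshold, one at the maximal myocardial
# intensity, negative below the threshold.

#' Build the level-set speed image
#'
#' `S = (I - t) / (I_max - t)` on myocardial voxels (NA elsewhere), where
#' `I_max` is the maximal myocardial intensity: S = 0 at the threshold,
#' S = 1 at `I_max`, S < 0 below the threshold.  When no myocardial voxel
#' exceeds the threshold the speed image carries an empty seed flag and the
#' downstream segmentation returns an empty core (no error).
#'
#' @param img corrected [image_stack].
#' @param myo_mask 3D logical myocardium mask.
#' @param threshold EM-derived optimal threshold t*.
#' @return object of class `speed_image`: `speed` (3D array), `myo_mask`,
#'   `threshold`, `i_max`, `empty` flag.
#' @export
build_speed <- function(img, myo_mask, threshold) {
  I <- img$intensities
  if (!any(myo_mask)) stop("empty myocardium mask")
  i_max <- max(I[myo_mask])
  empty <- threshold >= i_max
  S <- array(NA_real_, dim(I))
  if (!empty)
    S[myo_mask] <- (I[myo_mask] - threshold) / (i_max - threshold)
  structure(list(speed = S, myo_mask = myo_mask, threshold = threshold,
                 i_max = i_max, empty = empty),
            class = "speed_image")
}

# In-slice curvature proxy on the discrete front: kappa = 1 - 2p where p is
# the region fraction of the 8-neighbourhood within the slice; neighbours
# outside the myocardium contribute a neutral 1/2.  kappa is +1 for an
# isolated voxel, 0 along a straight front, -1 inside a concavity.
#' @noRd
front_curvature <- function(region, myo) {
  d <- dim(region)
  inside <- array(0, d)
  denom <- array(0, d)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    m <- shift3d(myo, dr, dc, 0, fill = FALSE)
    r <- shift3d(region, dr, dc, 0, fill = FALSE)
    inside <- inside + ifelse(m, r, 0.5)
    denom <- denom + 1
  }
  1 - 2 * inside / denom
}

#' Segment the infarct core with a discrete level set
#'
#' Deterministic narrow-band evolution on the voxel grid, initialized at
#' the seed set (all voxels with positive speed, i.e. above the EM
#' threshold).  Each sweep the interface moves outward where
#' `S - alpha * kappa > 0` (candidate voxels 6-adjacent in 3D to the
#' region) and inward where `S - alpha * kappa < 0` (front voxels), with
#' kappa the in-slice discrete mean curvature; additions and removals are
#' computed simultaneously from the current region.  Evolution stops when a
#' full sweep changes nothing or at the iteration cap.  A voxel with S = 0
#' exactly is excluded (strict inequality), and with `alpha = 0` the output
#' equals direct thresholding `{S > 0}`.  The result is always a subset of
#' the myocardium.
#'
#' @param speed [speed_image] from [build_speed].
#' @param alpha curvature smoothing weight (speed units per curvature unit).
#' @param max_iter sweep cap.
#' @return 3D logical core mask.
#' @export
segment_core <- function(speed, alpha = 0.1, max_iter = 200L) {
  myo <- speed$myo_mask
  d <- dim(myo)
  if (speed$empty) return(array(FALSE, d))
  S <- speed$speed
  S0 <- ifelse(is.na(S), -Inf, S)
  region <- !is.na(S) & S > 0  # seeds
  if (!any(region)) return(region)
  offs6 <- neighbour_offsets(3L, 6L)
  for (it in seq_len(max_iter)) {
    nb <- array(FALSE, d)   # voxels 6-adjacent to the region
    for (k in seq_len(nrow(offs6)))
      nb <- nb | shift3d(region, offs6[k, 1], offs6[k, 2], offs6[k, 3])
    candidates <- nb & myo & !region
    front <- region & !(
      shift3d(region, 1, 0, 0, fill = TRUE) &
      shift3d(region, -1, 0, 0, fill = TRUE) &
      shift3d(region, 0, 1, 0, fill = TRUE) &
      shift3d(region, 0, -1, 0, fill = TRUE) &
      shift3d(region, 0, 0, 1, fill = TRUE) &
      shift3d(region, 0, 0, -1, fill = TRUE))
    if (alpha == 0) {
      force <- S0
    } else {
      kappa <- front_curvature(region, myo)
      force <- S0 - alpha * kappa
    }
    add <- candidates & force > 0
    remove <- front & force < 0
    if (!any(add) && !any(remove)) break
    region <- (region & !remove) | add
  }
  region & myo
}
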