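#' Short-axis LGE image stack
#'
#' Container for a short-axis late gadolinium enhancement image stack with
#' its voxel geometry and acquisition mode.  Intensities are stored as a 3D
#' array dimensioned (row, col, slice); slice 1 is the most basal slice.
#'
#' @param intensities numeric 3D array (row, col, slice) of finite values.
#'   A matrix is promoted to a single-slice stack.
#' @param pixel_spacing in-plane pixel size in mm (isotropic row/col).
#' @param slice_thickness slice thickness in mm.
#' @param slice_gap gap between slices in mm (0 for the typical
#'   gapless acquisition).
#' @param mode acquisition mode: `"IR"` (magnitude inversion recovery),
#'   `"PSIR"` (phase-sensitive IR) or `"T1w"` (high-resolution T1-weighted).
#' @return object of class `image_stack`.
#' @examples
#' img <- image_stack(array(rnorm(16 * 16 * 3, 50, 5), c(16, 16, 3)),
#'                    pixel_spacing = 1.5, slice_thickness = 8)
#' voxel_volume(img)
#' @export
image_stack <- function(intensities, pixel_spacing, slice_thickness,
                        slice_gap = 0, mode = c("IR", "PSIR", "T1w")) {
  mode <- match.arg(mode)
  if (is.matrix(intensities))
    intensities <- array(intensities, c(dim(intensities), 1L))
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array (row, col, slice)")
  if (dim(intensities)[3] < 1L) stop("at least 1 slice required")
  if (!all(is.finite(intensities))) stop("all intensities must be finite")
  if (!is.numeric(pixel_spacing) || pixel_spacing <= 0)
    stop("pixel_spacing must be > 0")
  if (!is.numeric(slice_thickness) || slice_thickness <= 0)
    stop("slice_thickness must be > 0")
  if (slice_gap < 0) stop("slice_gap must be >= 0")
  structure(
    list(intensities = intensities,
         pixel_spacing = pixel_spacing,
         slice_thickness = slice_thickness,
         slice_gap = slice_gap,
         mode = mode),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<image_stack> %d x %d x %d slices, %s mode, %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], x$mode, x$pixel_spacing, x$pixel_spacing,
              x$slice_thickness + x$slice_gap))
  invisible(x)
}

#' Voxel volume of an image stack
#'
#' `pixel_spacing^2 * (slice_thickness + slice_gap)` in mm^3; the slice gap
#' is attributed to the slice so stack volume integrates contiguous coverage.
#'
#' @param x an [image_stack] or a list with the geometry fields.
#' @return voxel volume in mm^3.
#' @export
voxel_volume <- function(x) {
  v <- x$pixel_spacing^2 * (x$slice_thickness + x$slice_gap)
  if (!is.finite(v) || v <= 0) stop("voxel volume must be > 0")
  v
}

#' Read an image stack from a NIfTI file
#'
#' Voxel geometry is taken from the NIfTI `pixdim` header; the in-plane
#' spacing must be isotropic.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param mode acquisition mode (not stored in NIfTI; supplied by the user).
#' @param slice_gap slice gap in mm if the pixdim z-step is the thickness only.
#' @return [image_stack]
#' @export
read_image_nifti <- function(path, mode = c("IR", "PSIR", "T1w"), slice_gap = 0) {
  mode <- match.arg(mode)
  nii <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(nii)
  arr <- as.array(nii)
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  if (abs(pd[1] - pd[2]) > 1e-6)
    stop("anisotropic in-plane spacing not supported")
  image_stack(arr, pixel_spacing = pd[1], slice_thickness = pd[3],
              slice_gap = slice_gap, mode = mode)
}

#' Write an image stack (or label map) to NIfTI
#'
#' @param x [image_stack], or a numeric/logical 3D array when `template`
#'   provides the geometry.
#' @param path output file path.
#' @param template optional [image_stack] supplying geometry for a bare array.
#' @export
write_image_nifti <- function(x, path, template = NULL) {
  if (inherits(x, "image_stack")) {
    arr <- x$intensities
    geom <- x
  } else {
    if (is.null(template)) stop("template image_stack required for bare arrays")
    arr <- x * 1  # logical -> numeric
    geom <- template
  }
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- c(geom$pixel_spacing, geom$pixel_spacing,
                           geom$slice_thickness + geom$slice_gap)
  RNifti::writeNifti(nii, path)
  invisible(path)
}
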