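#' Rasterize endo/epicardial contours to a myocardium slice mask
#'
#' Pixel-center point-in-polygon rasterization.  A pixel belongs to the
#' myocardium when its center lies inside or on the epicardial contour and
#' not strictly inside the endocardial contour: both the endocardial and the
#' epicardial boundary themselves count as myocardium, which maximizes the
#' myocardial mask consistently across slices.  Contours are closed polygons
#' in continuous pixel coordinates (x = column, y = row, integer values at
#' pixel centers).
#'
#' @param endo n x 2 matrix of (x, y) endocardial vertices.
#' @param epi n x 2 matrix of (x, y) epicardial vertices.
#' @param grid_shape c(nrow, ncol) of the slice grid.
#' @return logical matrix: TRUE on myocardial pixels.
#' @export
rasterize_contours <- function(endo, epi, grid_shape) {
  endo <- as.matrix(endo); epi <- as.matrix(epi)
  if (nrow(endo) < 3L || nrow(epi) < 3L)
    stop("degenerate polygon: contours need at least 3 vertices")
  if (isTRUE(all.equal(dim(endo), dim(epi))) &&
      max(abs(endo - epi)) < 1e-9)
    stop("geometry error: endocardial and epicardial contours coincide")
  # every endo vertex must lie strictly inside the epicardial polygon
  inside <- pracma::inpolygon(endo[, 1], endo[, 2], epi[, 1], epi[, 2],
                              boundary = FALSE)
  if (!all(inside))
    stop("geometry error: endocardial contour not strictly inside epicardial contour")
  nr <- grid_shape[1]; nc <- grid_shape[2]
  px <- rep(seq_len(nc), each = nr)   # x = column
  py <- rep(seq_len(nr), times = nc)  # y = row
  in_epi <- pracma::inpolygon(px, py, epi[, 1], epi[, 2], boundary = TRUE)
  in_endo <- pracma::inpolygon(px, py, endo[, 1], endo[, 2], boundary = FALSE)
  matrix(in_epi & !in_endo, nr, nc)
}

# Strict interior of a polygon on a pixel grid (blood pool rasterization).
#' @noRd
rasterize_interior <- function(poly, grid_shape) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  px <- rep(seq_len(nc), each = nr)
  py <- rep(seq_len(nr), times = nc)
  matrix(pracma::inpolygon(px, py, poly[, 1], poly[, 2], boundary = FALSE),
         nr, nc)
}

#' Left-ventricular segmentation from per-slice contours
#'
#' Builds the myocardial voxel mask (epicardium minus endocardium, see
#' [rasterize_contours]), the strict blood-pool mask, and the per-slice LV
#' center (centroid of the endocardial contour vertices).  Papillary-muscle
#' exclusion is the contourer's responsibility; masks are taken as given.
#'
#' @param contours list of length n_slices; each element either `NULL`
#'   (no myocardium on that slice) or `list(endo = <n x 2>, epi = <n x 2>)`.
#' @param grid_shape c(nrow, ncol) of each slice.
#' @return object of class `lv_segmentation` with fields `contours`,
#'   `myocardium_mask` (3D logical), `blood_mask` (3D logical, strict
#'   endocardial interior) and `lv_center` (n_slices x 2 matrix of (x, y),
#'   NA on slices without contours).
#' @export
lv_segmentation <- function(contours, grid_shape) {
  ns <- length(contours)
  if (ns < 1L) stop("at least one slice required")
  myo <- array(FALSE, c(grid_shape, ns))
  blood <- array(FALSE, c(grid_shape, ns))
  centers <- matrix(NA_real_, ns, 2L, dimnames = list(NULL, c("x", "y")))
  for (s in seq_len(ns)) {
    cs <- contours[[s]]
    if (is.null(cs)) next
    myo[, , s] <- rasterize_contours(cs$endo, cs$epi, grid_shape)
    blood[, , s] <- rasterize_interior(as.matrix(cs$endo), grid_shape)
    centers[s, ] <- colMeans(as.matrix(cs$endo))
  }
  if (!any(myo)) stop("myocardial voxel count is zero")
  structure(
    list(contours = contours,
         myocardium_mask = myo,
         blood_mask = blood,
         lv_center = centers),
    class = "lv_segmentation")
}

#' @export
print.lv_segmentation <- function(x, ...) {
  cat(sprintf("<lv_segmentation> %d slices, %d myocardial voxels\n",
              dim(x$myocardium_mask)[3], sum(x$myocardium_mask)))
  invisible(x)
}

#' Myocardial volume
#'
#' Volume of the myocardial mask in mm^3 (true-voxel count times voxel
#' volume).  LV mass is proportional to this volume; the tissue density
#' cancels when infarct size is expressed as a percentage of LV mass.
#'
#' @param seg [lv_segmentation]
#' @param geom object with voxel geometry ([image_stack] or compatible list).
#' @return volume in mm^3.
#' @export
myocardial_volume <- function(seg, geom) {
  n <- sum(seg$myocardium_mask)
  if (n == 0L) stop("empty myocardial mask")
  n * voxel_volume(geom)
}

#' Read / write per-slice contours as JSON
#'
#' Schema: `{"slices": [{"slice": i, "endo": [[x, y], ...],
#' "epi": [[x, y], ...]}, ...], "n_slices": n}`.  Slices absent from the
#' file carry no contours.
#'
#' @param path JSON file path.
#' @param contours contour list as accepted by [lv_segmentation].
#' @return `read_contours`: contour list; `write_contours`: `path`, invisibly.
#' @export
read_contours <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  ns <- obj$n_slices
  out <- vector("list", ns)
  sl <- obj$slices
  for (k in seq_len(nrow(sl))) {
    i <- sl$slice[k]
    out[[i]] <- list(endo = matrix(unlist(sl$endo[k]), ncol = 2L),
                     epi = matrix(unlist(sl$epi[k]), ncol = 2L))
  }
  out
}

#' @rdname read_contours
#' @export
write_contours <- function(contours, path) {
  idx <- which(!vapply(contours, is.null, logical(1)))
  slices <- lapply(idx, function(i)
    list(slice = i,
         endo = unname(as.matrix(contours[[i]]$endo)),
         epi = unname(as.matrix(contours[[i]]$epi))))
  jsonlite::write_json(list(n_slices = length(contours), slices = slices),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
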