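# Step 5: post-processing of the infarct segmentation -- remove bright
# regions outside the culprit artery's territory and discard small
# isolated regions.

#' Remove infarct voxels outside the culprit territory
#'
#' With a maximal-extent model, voxels whose (ring, sector) is not included
#' in the model are removed from the infarct mask.  Without a model
#' (experimental mode) the mask is returned unchanged.
#'
#' @param mask 3D logical infarct mask.
#' @param assign [sector_assignment] covering the mask.
#' @param model [max_extent_model] or `NULL`.
#' @return filtered 3D logical mask.
#' @export
filter_culprit <- function(mask, assign, model = NULL) {
  if (is.null(model)) return(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(mask)
  rs <- cbind(assign$ring[idx], assign$sector[idx])
  if (any(rs == 0L))
    stop("internal error: infarct voxel without sector assignment")
  keep <- model$included[rs]
  out <- array(FALSE, dim(mask))
  out[idx[keep]] <- TRUE
  out
}

#' Remove small isolated infarct regions
#'
#' Connected components (3D, 26-connectivity, so a contiguous transmural
#' infarct spanning slices counts as one region; MVO voxels belong to their
#' component) smaller than 1.5 cm^3 are removed, unless the component
#' comprises more than 1% of the LV mass or is the only region of infarct.
#' If the rule would remove every region of a non-empty mask, the largest
#' region is retained.
#'
#' @param mask 3D logical infarct mask (core plus MVO).
#' @param geom voxel geometry ([image_stack] or compatible).
#' @param lv_volume myocardial volume in mm^3 (see [myocardial_volume]).
#' @param min_volume_mm3 size threshold (default 1500 mm^3 = 1.5 cm^3).
#' @param max_pct_lvm LV-mass percentage above which a small region is
#'   still kept (default 1).
#' @return filtered 3D logical mask.
#' @export
remove_small_regions <- function(mask, geom, lv_volume,
                                 min_volume_mm3 = 1500, max_pct_lvm = 1) {
  if (lv_volume <= 0) stop("LV volume must be > 0")
  if (!any(mask)) return(mask)
  labels <- label_components(mask, connectivity = 26L)
  nlab <- max(labels)
  if (nlab == 1L) return(mask)  # the only region of MI is always kept
  vv <- voxel_volume(geom)
  vols <- tabulate(labels[labels > 0], nbins = nlab) * vv
  drop <- vols < min_volume_mm3 & vols <= (max_pct_lvm / 100) * lv_volume
  if (all(drop)) drop[which.max(vols)] <- FALSE
  out <- array(FALSE, dim(mask))
  out[labels > 0 & !drop[pmax(labels, 1L)]] <- TRUE
  out & mask
}
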