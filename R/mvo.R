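# Step 4: microvascular obstruction (MVO).  MVO appears as hypointense
# regions inside acute infarcts and is missed by intensity thresholding;
# it is recovered slice by slice as holes in the infarct region via flood
# fill, combined with a morphological closing (3x3 cross kernel) that seals
# small gaps before re-running the hole search.

# Classify the 4-connected non-core components of one slice: a component is
# a hole (MVO candidate) when every boundary contact is an infarct-core
# voxel or the endocardial border (blood pool), with at least one core
# contact; a contact with anything else (epicardial side, background, grid
# edge) means the flood fill "escapes" and the component is not MVO.
#' @noRd
find_holes_slice <- function(core, myo, blood) {
  noncore <- myo & !core
  if (!any(noncore)) return(matrix(FALSE, nrow(core), ncol(core)))
  labels <- EBImage::bwlabel(noncore * 1L)  # 4-connectivity
  nlab <- max(labels)
  bad <- logical(nlab)
  touches_core <- logical(nlab)
  for (sh in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nb_core <- shift2d(core, sh[1], sh[2], fill = FALSE)
    nb_blood <- shift2d(blood, sh[1], sh[2], fill = FALSE)
    nb_in <- shift2d(matrix(TRUE, nrow(core), ncol(core)), sh[1], sh[2],
                     fill = FALSE)
    nb_self <- shift2d(labels > 0, sh[1], sh[2], fill = FALSE)
    contact <- labels > 0 & !nb_self          # neighbour outside the component set
    esc <- contact & !(nb_core | nb_blood) | (labels > 0 & !nb_in)
    hit <- contact & nb_core
    if (any(esc)) bad[unique(labels[esc])] <- TRUE
    if (any(hit)) touches_core[unique(labels[hit])] <- TRUE
  }
  ok <- which(!bad & touches_core)
  matrix(labels %in% ok, nrow(core), ncol(core))
}

#' Detect microvascular obstruction on one slice
#'
#' Three passes: (a) flood fill labels the non-core myocardial components
#' and keeps those totally surrounded by infarct core or sealed against the
#' endocardial border; (b) the core is dilated with a 3x3 cross-shaped
#' kernel to close 1-pixel gaps and the flood fill is re-run on the dilated
#' core to find holes created by the closing (the erosion completing the
#' closing is applied to the core, not the holes); (c) the union of both
#' hole sets, minus the core, is the slice MVO mask.
#'
#' @param core logical matrix: infarct core on this slice.
#' @param myo logical matrix: myocardium on this slice.
#' @param blood logical matrix: blood pool (strict endocardial interior).
#' @return logical matrix: MVO voxels on this slice.
#' @export
detect_mvo_slice <- function(core, myo, blood) {
  if (!any(core)) return(matrix(FALSE, nrow(core), ncol(core)))
  holes_a <- find_holes_slice(core, myo, blood)
  core_d <- (EBImage::dilate(core * 1L, cross_kernel()) > 0) & myo
  holes_b <- find_holes_slice(core_d, myo, blood)
  (holes_a | holes_b) & !core
}

#' Detect microvascular obstruction slice by slice
#'
#' @param core 3D logical infarct-core mask.
#' @param seg [lv_segmentation] (supplies myocardium and blood-pool masks).
#' @return 3D logical MVO mask (always within myocardium, outside the core).
#' @export
detect_mvo <- function(core, seg) {
  d <- dim(core)
  out <- array(FALSE, d)
  for (s in seq_len(d[3]))
    out[, , s] <- detect_mvo_slice(core[, , s], seg$myocardium_mask[, , s],
                                   seg$blood_mask[, , s])
  out
}

#' Merge infarct core and MVO into the combined infarct mask
#'
#' MVO represents 100% infarcted tissue: its voxels join the infarct mask
#' and are flagged for weight-1 treatment in the weighted summation.
#'
#' @param core 3D logical core mask.
#' @param mvo 3D logical MVO mask; must be disjoint from `core`.
#' @return list with `mask` (union) and `mvo` (flag mask).
#' @export
merge_infarct <- function(core, mvo) {
  if (any(core & mvo))
    stop("internal consistency error: core and MVO masks overlap")
  list(mask = core | mvo, mvo = mvo)
}
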