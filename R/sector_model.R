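# Extended bulls-eye sector model: 9 rings (3 basal, 3 mid-ventricular,
# 3 apical) x 24 equal 15-degree sectors per slice, anchored on the
# right-ventricular insertion points supplied by the user.

N_RINGS <- 9L
N_SECTORS <- 24L

#' Right-ventricular insertion points
#'
#' The anterior and inferior RV insertion points define the rotation of the
#' left ventricle: sector 1 starts at the anterior insertion angle and
#' sector indices increase through the septum toward the inferior insertion.
#' One pair applies to the whole stack.
#'
#' @param anterior,inferior numeric (x, y) in pixel coordinates.
#' @return object of class `insertion_points`.
#' @export
insertion_points <- function(anterior, inferior) {
  anterior <- as.numeric(anterior); inferior <- as.numeric(inferior)
  if (length(anterior) != 2L || length(inferior) != 2L)
    stop("insertion points must be (x, y) pairs")
  if (max(abs(anterior - inferior)) < 1e-9)
    stop("anterior and inferior insertion points coincide")
  structure(list(anterior = anterior, inferior = inferior),
            class = "insertion_points")
}

# Ring index (1 = most basal) for slice s of S; proportional midpoint rule so
# any slice count maps onto the 9-ring model (9 slices -> rings 1..9).
#' @noRd
slice_ring <- function(s, n_slices) {
  r <- floor((s - 0.5) * N_RINGS / n_slices) + 1L
  clamp(as.integer(r), 1L, N_RINGS)
}

#' Assign myocardial voxels to bulls-eye rings and sectors
#'
#' Rings: slices are mapped proportionally onto the 9 rings (slice 1 =
#' basal, last slice = apical); with exactly 9 slices the mapping is the
#' identity.  Sectors: 24 half-open 15-degree angular bins about the
#' per-slice LV center, with bin 1 starting at the anterior insertion angle
#' and indices increasing in the direction of the shorter arc toward the
#' inferior insertion, so septal sectors carry low indices.
#'
#' @param seg [lv_segmentation]
#' @param ins [insertion_points]
#' @return object of class `sector_assignment` with integer arrays `ring`
#'   and `sector` (0 outside the myocardium) shaped like the myocardial mask.
#' @export
assign_sectors <- function(seg, ins) {
  stopifnot(inherits(seg, "lv_segmentation"), inherits(ins, "insertion_points"))
  myo <- seg$myocardium_mask
  d <- dim(myo)
  ring <- array(0L, d)
  sector <- array(0L, d)
  ns <- d[3]
  for (s in seq_len(ns)) {
    m <- myo[, , s]
    if (!any(m)) next
    ctr <- seg$lv_center[s, ]
    if (any(is.na(ctr))) ctr <- c(mean(col(m)[m]), mean(row(m)[m]))
    if (max(abs(ins$anterior - ctr)) < 1e-9 && max(abs(ins$inferior - ctr)) < 1e-9)
      stop("insertion points coincide with the LV center")
    th_a <- atan2(ins$anterior[2] - ctr[2], ins$anterior[1] - ctr[1]) * 180 / pi
    th_i <- atan2(ins$inferior[2] - ctr[2], ins$inferior[1] - ctr[1]) * 180 / pi
    delta <- (th_i - th_a) %% 360
    direction <- if (delta <= 180) 1 else -1
    idx <- which(m)
    x <- col(m)[idx]; y <- row(m)[idx]
    th <- atan2(y - ctr[2], x - ctr[1]) * 180 / pi
    rel <- (direction * (th - th_a)) %% 360
    # snap to exact bin edges within float tolerance so voxels lying on a
    # 15-degree boundary are assigned consistently (half-open bins) under
    # rigid transformations of the whole geometry
    snap <- round(rel / 15) * 15
    on_edge <- abs(rel - snap) < 1e-9
    rel[on_edge] <- snap[on_edge]
    rel[rel >= 360] <- 0
    sec <- pmin(as.integer(floor(rel / 15)) + 1L, N_SECTORS)
    sl <- matrix(0L, d[1], d[2])
    sl[idx] <- sec
    sector[, , s] <- sl
    ring[, , s][m] <- slice_ring(s, ns)
  }
  structure(list(ring = ring, sector = sector, n_slices = ns),
            class = "sector_assignment")
}

#' Maximal-extent perfusion-territory model
#'
#' A boolean inclusion map over the 9 x 24 extended bulls-eye describing the
#' maximal perfusion territory of one culprit artery.  The LM model is the
#' union of the LAD, LCx and RCA models.
#'
#' @param artery one of `"LAD"`, `"LCx"`, `"RCA"`, `"LM"`.
#' @param included 9 x 24 logical matrix (ring x sector).
#' @return object of class `max_extent_model`.
#' @export
max_extent_model <- function(artery, included) {
  artery <- match.arg(artery, c("LAD", "LCx", "RCA", "LM"))
  included <- matrix(as.logical(included), N_RINGS, N_SECTORS)
  if (!any(included)) stop("extent model must include at least one sector")
  structure(list(artery = artery, included = included),
            class = "max_extent_model")
}

#' Remote-myocardium mask from an extent model
#'
#' Remote myocardium = myocardial voxels whose (ring, sector) lies outside
#' the culprit artery's maximal extent model.  It is the normal-intensity
#' reference for coil correction and the n-SD comparators.
#'
#' @param seg [lv_segmentation]
#' @param assign [sector_assignment]
#' @param model [max_extent_model]
#' @return 3D logical mask.
#' @export
remote_mask <- function(seg, assign, model) {
  myo <- seg$myocardium_mask
  idx <- which(myo)
  inc <- model$included[cbind(assign$ring[idx], assign$sector[idx])]
  out <- array(FALSE, dim(myo))
  out[idx[!inc]] <- TRUE
  if (!any(out))
    stop("degenerate extent model: no remote myocardium left")
  out
}

# Territory (non-remote) mask; complement of remote within the myocardium.
#' @noRd
territory_mask <- function(seg, assign, model) {
  seg$myocardium_mask & !remote_mask(seg, assign, model)
}

#' Load maximal-extent models from a YAML/JSON config
#'
#' Schema: per artery a list of `[ring, sector]` pairs (ring 1-9, sector
#' 1-24).  LAD, LCx and RCA are required; LM is derived as their union if
#' absent and validated against the union if present.  The bundled default
#' config (`system.file("extdata", "extent_models.yaml", package =
#' "ewamri")`) approximates the standard qualitative territories
#' (LAD anterior + anteroseptal + apex, RCA inferior + inferoseptal, LCx
#' lateral) and is replaceable configuration, not validated truth.
#'
#' @param path config file (.yaml/.yml or .json); default: bundled config.
#' @return named list of [max_extent_model]s (LAD, LCx, RCA, LM).
#' @export
load_extent_models <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "extent_models.yaml", package = "ewamri")
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyMatrix = FALSE)
  for (a in c("LAD", "LCx", "RCA"))
    if (is.null(cfg[[a]]))
      stop("extent-model config is missing artery ", a)
  parse_one <- function(a) {
    pairs <- cfg[[a]]
    inc <- matrix(FALSE, N_RINGS, N_SECTORS)
    for (k in seq_along(pairs)) {
      p <- unlist(pairs[[k]])
      if (length(p) != 2L || any(p != round(p)))
        stop(sprintf("malformed [ring, sector] entry %d for artery %s", k, a))
      if (p[1] < 1 || p[1] > N_RINGS || p[2] < 1 || p[2] > N_SECTORS)
        stop(sprintf("entry %d for artery %s out of range: [%d, %d]",
                     k, a, p[1], p[2]))
      inc[p[1], p[2]] <- TRUE
    }
    max_extent_model(a, inc)
  }
  models <- lapply(c(LAD = "LAD", LCx = "LCx", RCA = "RCA"), parse_one)
  union_inc <- models$LAD$included | models$LCx$included | models$RCA$included
  if (is.null(cfg$LM)) {
    models$LM <- max_extent_model("LM", union_inc)
  } else {
    models$LM <- parse_one("LM")
    if (!identical(models$LM$included, union_inc))
      stop("LM model must equal the union of LAD, LCx and RCA")
  }
  models
}

#' Save maximal-extent models to a YAML config
#'
#' @param models named list of [max_extent_model]s.
#' @param path output .yaml path.
#' @export
save_extent_models <- function(models, path) {
  enc <- lapply(models, function(m) {
    idx <- which(m$included, arr.ind = TRUE)
    lapply(seq_len(nrow(idx)), function(k) as.integer(idx[k, ]))
  })
  yaml::write_yaml(enc, path)
  invisible(path)
}
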