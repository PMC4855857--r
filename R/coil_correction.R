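# Step 1: surface-coil intensity correction.  Signal drop-off with coil
# distance is modelled as a smooth multiplicative field; a second-order
# polynomial surface (1, x, y, x^2, xy, y^2) captures a gradient
# proportional to the squared coil distance.  The field is fit by least
# squares to class-normalized intensities of two reference tissues with
# (ideally) spatially constant true signal: the blood pool and the remote
# myocardium.

# Second-order design matrix at normalized coordinates.
#' @noRd
poly2_design <- function(xn, yn) cbind(1, xn, yn, xn^2, xn * yn, yn^2)

#' Fit a surface-coil intensity correction field
#'
#' Each sample voxel contributes `intensity / mean(class)` (class = blood or
#' remote), i.e. its intensity relative to its tissue class; the smooth
#' multiplicative coil field is the least-squares second-order polynomial
#' surface through these relative intensities, fit per slice in 2D.  Slices
#' with fewer than 6 usable samples trigger a pooled fit (one surface shared
#' by all slices); a rank-deficient design falls back to a first-order
#' surface with a warning.  The field is normalized to mean 1 over the fit
#' samples.
#'
#' @param img [image_stack]
#' @param blood_mask 3D logical: blood-pool samples (endocardial interior,
#'   typically eroded 1 pixel to avoid boundary partial volume).
#' @param remote_mask 3D logical: remote-myocardium samples.
#' @param myo_mask optional 3D logical; the fitted field must be strictly
#'   positive there.
#' @return object of class `correction_field`: `field` (3D array),
#'   `coefficients` (n_slices x 6), `pooled` flag.
#' @export
fit_correction <- function(img, blood_mask, remote_mask, myo_mask = NULL) {
  I <- img$intensities
  d <- dim(I)
  if (!any(blood_mask) || !any(remote_mask))
    stop("blood and remote masks must be non-empty")
  mb <- mean(I[blood_mask]); mr <- mean(I[remote_mask])
  rel <- array(NA_real_, d)
  rel[blood_mask] <- I[blood_mask] / mb
  rel[remote_mask] <- I[remote_mask] / mr
  samp <- blood_mask | remote_mask
  cx <- (d[2] + 1) / 2; cy <- (d[1] + 1) / 2
  sx <- d[2] / 2; sy <- d[1] / 2
  norm_xy <- function(idx2d) {
    x <- ((idx2d - 1) %/% d[1]) + 1
    y <- ((idx2d - 1) %% d[1]) + 1
    cbind((x - cx) / sx, (y - cy) / sy)
  }
  per_slice_n <- vapply(seq_len(d[3]), function(s) sum(samp[, , s]), integer(1))
  pooled <- any(per_slice_n < 6L)
  fit_ls <- function(X, yv) {
    q <- qr(X)
    if (q$rank < ncol(X)) {
      warning("rank-deficient coil-correction design; falling back to first order")
      X1 <- X[, 1:3, drop = FALSE]
      b <- qr.coef(qr(X1), yv)
      return(c(b, 0, 0, 0))
    }
    qr.coef(q, yv)
  }
  coefs <- matrix(NA_real_, d[3], 6L)
  if (pooled) {
    idx_all <- which(samp)
    if (length(idx_all) < 6L)
      stop("fewer than 6 usable coil-correction samples; fit underdetermined")
    idx2d <- ((idx_all - 1) %% (d[1] * d[2])) + 1
    xy <- norm_xy(idx2d)
    b <- fit_ls(poly2_design(xy[, 1], xy[, 2]), rel[idx_all])
    for (s in seq_len(d[3])) coefs[s, ] <- b
  } else {
    for (s in seq_len(d[3])) {
      idx2d <- which(samp[, , s])
      xy <- norm_xy(idx2d)
      coefs[s, ] <- fit_ls(poly2_design(xy[, 1], xy[, 2]),
                           rel[, , s][idx2d])
    }
  }
  # evaluate field on the full grid
  gx <- rep(seq_len(d[2]), each = d[1]); gy <- rep(seq_len(d[1]), d[2])
  Xg <- poly2_design((gx - cx) / sx, (gy - cy) / sy)
  field <- array(NA_real_, d)
  for (s in seq_len(d[3])) field[, , s] <- matrix(Xg %*% coefs[s, ], d[1], d[2])
  z <- mean(field[samp])
  field <- field / z
  coefs <- coefs / z
  check <- samp | (myo_mask %||% array(FALSE, d))
  if (any(field[check] <= 0))
    stop("fitted correction field is non-positive over the myocardium")
  structure(list(field = field, coefficients = coefs, pooled = pooled,
                 check_mask = check),
            class = "correction_field")
}

#' Apply a correction field to an image stack
#'
#' Corrected intensity = intensity / field, elementwise; the acquisition
#' mode is preserved.  Division by a positive field never changes the sign
#' of PSIR intensities.
#'
#' @param img [image_stack]
#' @param field [correction_field] from [fit_correction].
#' @return corrected [image_stack].
#' @export
apply_correction <- function(img, field) {
  stopifnot(inherits(field, "correction_field"))
  if (any(field$field[field$check_mask] <= 0))
    stop("correction field non-positive inside the myocardium")
  out <- img
  out$intensities <- img$intensities / field$field
  out
}

# Identity correction field (used when no extent model is supplied and the
# coil-correction step is skipped).
#' @noRd
identity_field <- function(dim3) {
  structure(list(field = array(1, dim3),
                 coefficients = matrix(rep(c(1, 0, 0, 0, 0, 0), dim3[3]),
                                       dim3[3], 6L, byrow = TRUE),
                 pooled = FALSE,
                 check_mask = array(TRUE, dim3)),
            class = "correction_field")
}
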