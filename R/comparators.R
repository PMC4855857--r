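# Classical comparator thresholds for benchmarking against the EWA
# pipeline on identical inputs: n-SD from remote, FWHM from the minimum or
# from the remote mean, Otsu's threshold, and the plain EM cut.  All
# comparator sizes are unweighted binary voxel counts, by definition.

# Shared wrap-up: binary cut of myocardial intensities at a threshold.
#' @noRd
cut_at <- function(img, myo_mask, threshold, method, warning_msg = NULL) {
  mask <- myo_mask & img$intensities > threshold
  structure(list(method = method, threshold = threshold, mask = mask,
                 pct_lvm = 100 * sum(mask) / sum(myo_mask),
                 warning = warning_msg),
            class = "comparator_result")
}

#' @export
print.comparator_result <- function(x, ...) {
  cat(sprintf("<%s> threshold %.4g -> %.2f %%LVM\n", x$method, x$threshold,
              x$pct_lvm))
  invisible(x)
}

#' n-SD-from-remote threshold
#'
#' Infarct = myocardial voxels with intensity above
#' `mean(remote) + n * sd(remote)`.  For purely Gaussian remote intensities
#' the 2SD and 3SD cuts flag the theoretical upper-tail fractions of about
#' 2% and 0.1% of normal voxels.
#'
#' @param img [image_stack]
#' @param myo_mask 3D logical myocardium mask.
#' @param remote 3D logical remote mask.
#' @param n number of standard deviations.
#' @return `comparator_result`: `threshold`, `mask`, `pct_lvm`.
#' @export
threshold_nsd <- function(img, myo_mask, remote, n) {
  x <- img$intensities[remote]
  if (length(x) == 0L) stop("empty remote mask")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("remote intensities have zero spread")
  cut_at(img, myo_mask, mean(x) + n * s, sprintf("%gSD", n))
}

#' FWHM threshold from the minimum intensity
#'
#' Half-maximum measured from the myocardial minimum:
#' `t = I_min + 0.5 (I_max - I_min)`.  Global myocardial extrema are used;
#' `from_region = TRUE` instead takes `I_max` within the largest connected
#' hyperenhanced region (26-connectivity above the global half-max), closer
#' to the original region-growing formulations.
#'
#' @param img [image_stack]
#' @param myo_mask 3D logical myocardium mask.
#' @param from_region take the maximum within the brightest connected region.
#' @return `comparator_result`.
#' @export
threshold_fwhm_min <- function(img, myo_mask, from_region = FALSE) {
  x <- img$intensities[myo_mask]
  if (max(x) - min(x) <= 0) stop("constant myocardial intensities")
  i_max <- if (from_region) region_max(img, myo_mask) else max(x)
  cut_at(img, myo_mask, min(x) + 0.5 * (i_max - min(x)), "FWHM-min")
}

#' FWHM threshold from the remote mean
#'
#' `t = mu_remote + 0.5 (I_max - mu_remote)`.  Developed for PSIR images; a
#' warning is raised when applied to magnitude-IR stacks.
#'
#' @inheritParams threshold_fwhm_min
#' @param remote 3D logical remote mask.
#' @return `comparator_result`.
#' @export
threshold_fwhm_remote <- function(img, myo_mask, remote, from_region = FALSE) {
  if (!any(remote)) stop("empty remote mask")
  mu_r <- mean(img$intensities[remote])
  i_max <- if (from_region) region_max(img, myo_mask)
           else max(img$intensities[myo_mask])
  if (i_max <= mu_r)
    stop("maximal myocardial intensity does not exceed the remote mean")
  msg <- NULL
  if (img$mode == "IR") {
    msg <- "FWHM-remote was designed for PSIR images; applying to IR mode"
    warning(msg)
  }
  cut_at(img, myo_mask, mu_r + 0.5 * (i_max - mu_r), "FWHM-remote", msg)
}

# Max intensity inside the largest connected supra-half-max region.
#' @noRd
region_max <- function(img, myo_mask) {
  x <- img$intensities
  half <- min(x[myo_mask]) + 0.5 * (max(x[myo_mask]) - min(x[myo_mask]))
  hyper <- myo_mask & x > half
  if (!any(hyper)) return(max(x[myo_mask]))
  lab <- label_components(hyper, 26L)
  big <- which.max(tabulate(lab[lab > 0]))
  max(x[lab == big])
}

#' Otsu's threshold over the myocardium
#'
#' Exhaustive search over a 256-bin histogram of the myocardial intensities
#' for the bin boundary maximizing the between-class variance.  A
#' `low_separation` flag is set when the between-class variance is small
#' relative to the total variance (effectively unimodal input).
#'
#' @param img [image_stack]
#' @param myo_mask 3D logical myocardium mask.
#' @param levels number of histogram bins.
#' @return `comparator_result` with extra field `low_separation`.
#' @export
threshold_otsu <- function(img, myo_mask, levels = 256L) {
  x <- img$intensities[myo_mask]
  if (length(unique(x)) < 2L) stop("need at least 2 distinct intensities")
  lo <- min(x); hi <- max(x)
  bin <- pmin(as.integer((x - lo) / (hi - lo) * levels) + 1L, levels)
  h <- tabulate(bin, nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  bcv <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bcv[!is.finite(bcv)] <- 0
  # classes {1..k} vs {k+1..}; ties across an empty inter-class gap are
  # broken at the middle of the maximizing run (mid-gap threshold)
  top <- which(bcv >= max(bcv) * (1 - 1e-12))
  k <- top[ceiling(length(top) / 2)]
  thr <- lo + k / levels * (hi - lo)
  res <- cut_at(img, myo_mask, thr, "Otsu")
  # separability eta = sigma_B^2 / sigma_T^2 is ~1 for well-separated
  # bimodal input, <= ~2/3 for a single Gaussian mode
  res$low_separation <- max(bcv) / stats::var(bin) < 0.75
  res
}

#' Plain EM threshold comparator
#'
#' The constrained EM fit of [em_fit] followed by a binary cut at the
#' optimal threshold -- the EWA core before level set, MVO inclusion,
#' post-processing and weighting.
#'
#' @param img [image_stack]
#' @param myo_mask 3D logical myocardium mask.
#' @param constraints [em_constraints]
#' @return `comparator_result` with extra field `pair` (the fitted
#'   [gaussian_pair]).
#' @export
threshold_em_pure <- function(img, myo_mask, constraints = em_constraints()) {
  pair <- em_fit(img$intensities[myo_mask], constraints)
  res <- cut_at(img, myo_mask, pair$threshold, "EM")
  res$pair <- pair
  res
}
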