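# End-to-end orchestration of the six pipeline steps, with configuration,
# logging and reproducible outputs.

#' Pipeline configuration
#'
#' All tunables in one place.  Percentile constraints (5/95/90) and the
#' post-processing thresholds (1.5 cm^3, 1 %LVM) are the published
#' operating points of the method; the level-set smoothing weight and
#' iteration caps are numerical defaults recorded in every result.
#'
#' @param alpha level-set curvature smoothing weight.
#' @param levelset_max_iter level-set sweep cap.
#' @param p_lo,p_hi,p_init EM percentile constraints (see [em_constraints]).
#' @param em_tol,em_max_iter EM convergence controls.
#' @param min_region_cm3 small-region volume threshold in cm^3.
#' @param max_region_pct_lvm LV-mass percentage protecting small regions.
#' @param weighted_threshold use the posterior-equality threshold (see
#'   [optimal_threshold]).
#' @return list of class `ewa_config`.
#' @export
ewa_config <- function(alpha = 0.1, levelset_max_iter = 200L,
                       p_lo = 5, p_hi = 95, p_init = 90,
                       em_tol = 1e-6, em_max_iter = 500L,
                       min_region_cm3 = 1.5, max_region_pct_lvm = 1,
                       weighted_threshold = TRUE) {
  structure(as.list(environment()), class = "ewa_config")
}

# Blood-pool sample mask for coil fitting: strict endocardial interior
# eroded by one pixel (3x3 box) to avoid boundary partial volume.
#' @noRd
blood_sample_mask <- function(seg) {
  b <- seg$blood_mask
  out <- array(FALSE, dim(b))
  box <- matrix(1, 3L, 3L)
  for (s in seq_len(dim(b)[3]))
    if (any(b[, , s]))
      out[, , s] <- EBImage::erode(b[, , s] * 1L, box) > 0
  out
}

#' Run the full EWA pipeline
#'
#' Executes the six steps in order: surface-coil intensity correction
#' (skipped, identity field, when no culprit artery is supplied -- the
#' remote reference then falls back to the EM normal-component mean);
#' constrained-EM thresholding of the myocardial intensities; level-set
#' growth of the core from supra-threshold seeds; slice-wise MVO
#' detection; post-processing (culprit-territory filter, small-region
#' removal); and partial-volume weighted summation.
#'
#' @param stack [image_stack]
#' @param seg [lv_segmentation]
#' @param culprit culprit artery (`"LAD"`, `"LCx"`, `"RCA"`, `"LM"`) or
#'   `NULL` for no-model (experimental) mode.
#' @param insertions [insertion_points]; required when `culprit` is given.
#' @param models named list of extent models (default: bundled config).
#' @param config [ewa_config]
#' @return object of class `ewa_result`: `infarct_pct_lvm` (weighted),
#'   `core_pct_lvm` (unweighted core + MVO), `mvo_volume_ml`, `threshold`,
#'   `em` ([gaussian_pair]), masks (`core_mask`, `mvo_mask`, `weight_map`),
#'   `remote_mean`, the `config`, and a per-step `log`.
#' @export
run_ewa <- function(stack, seg, culprit = NULL, insertions = NULL,
                    models = NULL, config = ewa_config()) {
  stopifnot(inherits(stack, "image_stack"), inherits(seg, "lv_segmentation"))
  myo <- seg$myocardium_mask
  log <- list()
  assign <- NULL; remote <- NULL; model <- NULL

  if (!is.null(culprit)) {
    if (is.null(insertions))
      stop("insertion points are required when a culprit artery is given")
    models <- models %||% load_extent_models()
    model <- models[[match.arg(culprit, names(models))]]
    assign <- assign_sectors(seg, insertions)
    remote <- remote_mask(seg, assign, model)
    log$remote <- list(n = sum(remote))
    # step 1: coil correction from blood pool + remote myocardium
    field <- fit_correction(stack, blood_sample_mask(seg), remote, myo)
    img <- apply_correction(stack, field)
    log$coil <- list(pooled = field$pooled)
  } else {
    img <- stack
    log$coil <- list(skipped = TRUE)
  }

  # step 2: constrained EM threshold
  constraints <- em_constraints(config$p_lo, config$p_hi, config$p_init)
  pair <- em_fit(img$intensities[myo], constraints,
                 tol = config$em_tol, max_iter = config$em_max_iter)
  tstar <- optimal_threshold(pair, weighted = config$weighted_threshold)
  log$em <- list(threshold = tstar, mu_n = pair$mu_n, mu_i = pair$mu_i,
                 iterations = pair$iterations, converged = pair$converged)

  # step 3: level-set core growth
  speed <- build_speed(img, myo, tstar)
  core <- segment_core(speed, alpha = config$alpha,
                       max_iter = config$levelset_max_iter)
  log$levelset <- list(seeds = sum(!is.na(speed$speed) & speed$speed > 0,
                                   na.rm = TRUE),
                       core = sum(core))

  # step 4: MVO
  mvo <- detect_mvo(core, seg)
  merged <- merge_infarct(core, mvo)
  log$mvo <- list(n = sum(mvo))

  # step 5: post-processing
  lv_vol <- myocardial_volume(seg, stack)
  mask <- filter_culprit(merged$mask, assign, model)
  n_before <- sum(mask)
  mask <- remove_small_regions(mask, stack, lv_vol,
                               min_volume_mm3 = config$min_region_cm3 * 1000,
                               max_pct_lvm = config$max_region_pct_lvm)
  log$postprocess <- list(removed_culprit = sum(merged$mask) - n_before,
                          removed_small = n_before - sum(mask))
  mvo_final <- merged$mvo & mask
  core_final <- mask & !mvo_final

  # step 6: weighted summation
  if (any(mask)) {
    mu_r <- if (!is.null(remote)) mean(img$intensities[remote]) else pair$mu_n
    w <- weight_map(img, core_final, mvo_final, mu_r)
    size_w <- infarct_size(w, seg, stack)
  } else {
    mu_r <- if (!is.null(remote)) mean(img$intensities[remote]) else pair$mu_n
    w <- array(0, dim(myo))
    size_w <- 0
  }
  vv <- voxel_volume(stack)
  structure(
    list(infarct_pct_lvm = size_w,
         core_pct_lvm = 100 * sum(mask) / sum(myo),
         mvo_volume_ml = sum(mvo_final) * vv / 1000,
         threshold = tstar,
         em = pair,
         core_mask = core_final,
         mvo_mask = mvo_final,
         weight_map = w,
         remote_mean = mu_r,
         mode = stack$mode,
         culprit = culprit,
         config = config,
         log = log),
    class = "ewa_result")
}

#' @export
print.ewa_result <- function(x, ...) {
  cat(sprintf(paste0("<ewa_result> infarct %.2f %%LVM (weighted), core+MVO ",
                     "%.2f %%LVM, MVO %.2f mL, t* = %.4g [%s%s]\n"),
              x$infarct_pct_lvm, x$core_pct_lvm, x$mvo_volume_ml, x$threshold,
              x$mode, if (is.null(x$culprit)) ", no extent model"
                      else paste0(", culprit ", x$culprit)))
  invisible(x)
}

#' Compare quantification methods on one input
#'
#' Runs the requested methods on identical inputs and tabulates the
#' threshold, infarct size in %LVM, and (when a reference mask is given)
#' the Dice similarity coefficient against it.  The n-SD and FWHM-remote
#' methods need a remote mask and are only available when `culprit` and
#' `insertions` (or an explicit `remote`) are supplied.
#'
#' @param stack [image_stack]
#' @param seg [lv_segmentation]
#' @param methods subset of `c("ewa", "em", "2sd", "3sd", "5sd",
#'   "fwhm-min", "fwhm-remote", "otsu")`.
#' @param culprit,insertions,models as in [run_ewa].
#' @param remote optional explicit remote mask (overrides the model-derived
#'   one).
#' @param reference optional reference infarct mask for DSC.
#' @param config [ewa_config]
#' @return data.frame with columns `method`, `threshold`, `pct_lvm`, `dsc`.
#' @export
run_compare <- function(stack, seg,
                        methods = c("ewa", "em", "2sd", "3sd", "5sd",
                                    "fwhm-min", "fwhm-remote", "otsu"),
                        culprit = NULL, insertions = NULL, models = NULL,
                        remote = NULL, reference = NULL,
                        config = ewa_config()) {
  valid <- c("ewa", "em", "2sd", "3sd", "5sd", "fwhm-min", "fwhm-remote",
             "otsu")
  bad <- setdiff(methods, valid)
  if (length(bad))
    stop("unknown method(s) ", paste(bad, collapse = ", "),
         "; valid: ", paste(valid, collapse = ", "))
  myo <- seg$myocardium_mask
  if (is.null(remote) && !is.null(culprit)) {
    models <- models %||% load_extent_models()
    assign <- assign_sectors(seg, insertions)
    remote <- remote_mask(seg, assign, models[[culprit]])
  }
  need_remote <- intersect(methods, c("2sd", "3sd", "5sd", "fwhm-remote"))
  if (length(need_remote) && is.null(remote))
    stop("methods ", paste(need_remote, collapse = ", "),
         " need a remote mask (supply culprit + insertions, or remote)")
  one <- function(m) {
    res <- switch(m,
      "ewa" = {
        r <- run_ewa(stack, seg, culprit, insertions, models, config)
        list(threshold = r$threshold, mask = r$weight_map > 0,
             pct = r$infarct_pct_lvm)
      },
      "em" = { r <- threshold_em_pure(stack, myo)
               list(threshold = r$threshold, mask = r$mask, pct = r$pct_lvm) },
      "2sd" = { r <- threshold_nsd(stack, myo, remote, 2)
                list(threshold = r$threshold, mask = r$mask, pct = r$pct_lvm) },
      "3sd" = { r <- threshold_nsd(stack, myo, remote, 3)
                list(threshold = r$threshold, mask = r$mask, pct = r$pct_lvm) },
      "5sd" = { r <- threshold_nsd(stack, myo, remote, 5)
                list(threshold = r$threshold, mask = r$mask, pct = r$pct_lvm) },
      "fwhm-min" = { r <- threshold_fwhm_min(stack, myo)
                     list(threshold = r$threshold, mask = r$mask,
                          pct = r$pct_lvm) },
      "fwhm-remote" = { r <- suppressWarnings(
                          threshold_fwhm_remote(stack, myo, remote))
                        list(threshold = r$threshold, mask = r$mask,
                             pct = r$pct_lvm) },
      "otsu" = { r <- threshold_otsu(stack, myo)
                 list(threshold = r$threshold, mask = r$mask,
                      pct = r$pct_lvm) })
    data.frame(method = m, threshold = res$threshold, pct_lvm = res$pct,
               dsc = if (is.null(reference)) NA_real_
                     else dice(res$mask, reference))
  }
  do.call(rbind, lapply(methods, one))
}

#' Write an EWA result to disk
#'
#' Writes a NIfTI label map (0 background, 1 infarct core, 2 MVO) and a
#' JSON report with the sizes, threshold, EM parameters and configuration.
#'
#' @param result [run_ewa] result.
#' @param stack the input [image_stack] (geometry for the label map).
#' @param prefix output path prefix; writes `<prefix>_labels.nii.gz` and
#'   `<prefix>_result.json`.
#' @return named character vector of the written paths, invisibly.
#' @export
write_ewa_result <- function(result, stack, prefix) {
  labels <- array(0L, dim(result$core_mask))
  labels[result$core_mask] <- 1L
  labels[result$mvo_mask] <- 2L
  nii_path <- paste0(prefix, "_labels.nii.gz")
  write_image_nifti(labels, nii_path, template = stack)
  json_path <- paste0(prefix, "_result.json")
  report <- list(
    infarct_pct_lvm = result$infarct_pct_lvm,
    core_pct_lvm = result$core_pct_lvm,
    mvo_volume_ml = result$mvo_volume_ml,
    threshold = result$threshold,
    em = result$em[c("mu_n", "sd_n", "mu_i", "sd_i", "pi_n", "pi_i",
                     "iterations", "converged")],
    remote_mean = result$remote_mean,
    mode = result$mode,
    culprit = result$culprit,
    config = unclass(result$config),
    package_version = as.character(utils::packageVersion("ewamri")))
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(labels = nii_path, result = json_path))
}
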