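#' Intensity statistics of an ADC ROI
#'
#' Eight statistics of the raw in-mask ADC values plus the intensity-histogram
#' mean. `mean`, `p25`, `p50`, `p75` and the (Fisher, population-moment)
#' `skewness` and excess `kurtosis` are computed on the raw values;
#' `ih_kurtosis`, `ih_variance` and `ih_mean` are intensity-histogram
#' statistics on the FBN-discretized grey levels (`n_bins_intensity` bins),
#' so that the histogram statistics are distinct from the raw-value ones.
#' A zero-variance ROI returns skewness and kurtosis of 0 by convention.
#'
#' @param adc_vol ADC [volume3d()] (1e-6 mm^2/s).
#' @param mask nonempty [mask3d()].
#' @param n_bins_intensity bins for the intensity histogram (default 64).
#' @return Named numeric vector of 9 statistics: `mean`, `p25`, `p50`, `p75`,
#'   `skewness`, `kurtosis`, `ih_kurtosis`, `ih_variance`, `ih_mean`.
#' @export
intensity_statistics <- function(adc_vol, mask, n_bins_intensity = 64L) {
  stopifnot(inherits(adc_vol, "volume3d"), inherits(mask, "mask3d"))
  v <- adc_vol$data[mask$data == 1L]
  if (length(v) == 0L) stop("mask is empty")
  mom_stats <- function(x) {
    m <- mean(x)
    m2 <- mean((x - m)^2)
    if (m2 <= 0) return(c(skew = 0, kurt = 0, var = m2, mean = m))
    c(skew = mean((x - m)^3) / m2^1.5,
      kurt = mean((x - m)^4) / m2^2 - 3,
      var = m2, mean = m)
  }
  raw <- mom_stats(v)
  q <- stats::quantile(v, c(.25, .5, .75), names = FALSE, type = 7)
  lev <- if (max(v) > min(v)) {
    pmin(n_bins_intensity,
         1 + floor(n_bins_intensity * (v - min(v)) / (max(v) - min(v))))
  } else rep(1, length(v))
  ih <- mom_stats(lev)
  c(mean = raw[["mean"]], p25 = q[1], p50 = q[2], p75 = q[3],
    skewness = raw[["skew"]], kurtosis = raw[["kurt"]],
    ih_kurtosis = ih[["kurt"]], ih_variance = ih[["var"]],
    ih_mean = ih[["mean"]])
}

#' Physical volume of a mask
#'
#' @param mask nonempty [mask3d()].
#' @return Volume in mm^3: foreground voxel count times voxel volume.
#' @export
roi_volume <- function(mask) {
  stopifnot(inherits(mask, "mask3d"))
  n <- mask_count(mask)
  if (n == 0L) stop("mask is empty")
  n * voxel_volume_mm3(mask)
}

#' Canonical names of the 92-feature radiomics vector
#'
#' The frozen public contract for feature CSVs and trained models: ROI volume;
#' 8 ADC intensity statistics; the ADC intensity-histogram mean; 25 GLCM
#' features for ADC then T2w; 16 GLRLM features for ADC then T2w.
#'
#' @return Character vector of length 92.
#' @export
feature_names <- function() {
  c("roi_volume_mm3",
    paste0("adc_stat_", c("mean", "p25", "p50", "p75", "skewness",
                          "kurtosis", "ih_kurtosis", "ih_variance")),
    "adc_stat_ih_mean",
    paste0("adc_glcm_", glcm_feature_names()),
    paste0("t2w_glcm_", glcm_feature_names()),
    paste0("adc_glrlm_", glrlm_feature_names()),
    paste0("t2w_glrlm_", glrlm_feature_names()))
}

# crop a volume (and mask) to the mask bounding box plus a margin (voxels),
# so per-lesion preprocessing does not touch the full field of view
crop_margin_vox <- function(vol, cfg) {
  ceiling(4 * cfg$sigma_mm / min(vol$spacing)) + 2L
}

crop_to_mask <- function(vol, mask, margin) {
  idx <- which(mask$data == 1L, arr.ind = TRUE)
  d <- dim(mask$data)
  lo <- pmax(1L, apply(idx, 2, min) - margin)
  hi <- pmin(d, apply(idx, 2, max) + margin)
  crop1 <- function(v, cls) {
    dat <- v$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    org <- v$origin + (lo - 1L) * v$spacing
    if (cls == "mask") mask3d(dat, v$spacing, org) else
      volume3d(dat, v$spacing, org)
  }
  list(crop = crop1, lo = lo, hi = hi)
}

#' Extract the 92-feature radiomics vector for one lesion
#'
#' Runs the full per-lesion chain on the bundle: Gaussian de-noising
#' (T2w and ADC, per `cfg$denoise_channels`), isotropic resampling (trilinear
#' for images, nearest neighbour for the mask), per-channel percentile
#' re-segmentation, FBN discretization, then assembles ROI volume, ADC
#' intensity statistics and GLCM/GLRLM texture features from both channels in
#' the canonical [feature_names()] order. T2w contributes texture features
#' only, because its intensities are not quantitative. Internally the bundle
#' is cropped to the mask bounding box plus a margin at least as wide as the
#' smoothing kernel, which leaves in-mask values unchanged.
#'
#' @param bundle validated [case_bundle()].
#' @param mask nonempty lesion [mask3d()] on the bundle grid.
#' @param cfg a [preprocess_config()].
#' @return Named numeric vector of 92 finite values.
#' @export
extract_feature_vector <- function(bundle, mask, cfg = preprocess_config()) {
  stopifnot(inherits(bundle, "case_bundle"), inherits(mask, "mask3d"))
  if (mask_count(mask) == 0L) stop("mask is empty")
  validate_bundle(case_bundle(bundle$t2w, bundle$adc, bundle$uptake,
                              bundle$prob, mask))
  cr <- crop_to_mask(bundle$t2w, mask, crop_margin_vox(bundle$t2w, cfg))
  t2w <- cr$crop(bundle$t2w, "vol")
  adc <- cr$crop(bundle$adc, "vol")
  msk <- cr$crop(mask, "mask")

  if (cfg$sigma_mm > 0) {
    adc_f <- if (cfg$denoise_channels == "both")
      denoise_gaussian(adc, cfg$sigma_mm) else adc
    t2w_f <- denoise_gaussian(t2w, cfg$sigma_mm)
  } else {
    adc_f <- adc; t2w_f <- t2w
  }
  adc_i <- resample_isotropic(adc_f, cfg$iso_spacing_mm, "trilinear")
  t2w_i <- resample_isotropic(t2w_f, cfg$iso_spacing_mm, "trilinear")
  msk_i <- resample_isotropic(msk, cfg$iso_spacing_mm, "nearest")
  if (mask_count(msk_i) == 0L) stop("mask empty after resampling")

  msk_adc <- resegment_roi(adc_i, msk_i, cfg$reseg_lo_pct, cfg$reseg_hi_pct)
  msk_t2w <- resegment_roi(t2w_i, msk_i, cfg$reseg_lo_pct, cfg$reseg_hi_pct)

  vol_mask <- if (cfg$volume_after_reseg) msk_adc else msk_i
  agg <- if (cfg$merge_matrices) "merge" else "average"

  stats9 <- intensity_statistics(adc_i, msk_adc, cfg$n_bins_intensity)
  adc_tex <- discretize_fbn(adc_i, msk_adc, cfg$n_bins_texture)
  t2w_tex <- discretize_fbn(t2w_i, msk_t2w, cfg$n_bins_texture)

  out <- c(roi_volume(vol_mask),
           stats9[c("mean", "p25", "p50", "p75", "skewness", "kurtosis",
                    "ih_kurtosis", "ih_variance")],
           stats9[["ih_mean"]],
           glcm_features(adc_tex, aggregate = agg),
           glcm_features(t2w_tex, aggregate = agg),
           glrlm_features(adc_tex, aggregate = agg),
           glrlm_features(t2w_tex, aggregate = agg))
  names(out) <- feature_names()
  if (any(!is.finite(out)))
    stop("non-finite feature values: ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

#' Write or read a feature table CSV
#'
#' One row per lesion, columns in the canonical [feature_names()] order,
#' preceded by `lesion_id`, `patient_id` and `label` when present. Values are
#' written at full precision.
#'
#' @param x data.frame with feature columns (and optional id/label columns).
#' @param path CSV path.
#' @return `write_feature_csv`: `path` invisibly. `read_feature_csv`: the
#'   data.frame.
#' @export
write_feature_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
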