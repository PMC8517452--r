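#' Preprocessing configuration
#'
#' Parameters of the image-processing chain applied to each lesion before
#' feature extraction: Gaussian de-noising, isotropic resampling, ROI
#' re-segmentation and fixed-bin-number (FBN) discretization. Defaults follow
#' the pipeline's reference protocol: sigma 0.5 mm, 0.5 mm isotropic voxels,
#' re-segmentation between the 1st and 99th in-ROI percentiles, 64 bins for
#' the intensity histogram and 32 bins for the texture matrices.
#'
#' @param sigma_mm Gaussian sigma in mm (0 disables de-noising).
#' @param iso_spacing_mm target isotropic voxel spacing in mm.
#' @param reseg_lo_pct,reseg_hi_pct re-segmentation percentiles (0-100).
#' @param n_bins_intensity bins for the intensity-histogram statistics.
#' @param n_bins_texture bins for GLCM/GLRLM discretization.
#' @param denoise_channels which channels get the Gaussian filter:
#'   `"both"` (T2w and ADC) or `"t2w"`.
#' @param volume_after_reseg logical: measure ROI volume on the
#'   re-segmented mask instead of the resampled anatomical mask.
#' @param merge_matrices logical: average the texture matrices over the 13
#'   directions before computing features (IBSI "merged" aggregation) instead
#'   of averaging per-direction features.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(sigma_mm = 0.5, iso_spacing_mm = 0.5,
                              reseg_lo_pct = 1, reseg_hi_pct = 99,
                              n_bins_intensity = 64L, n_bins_texture = 32L,
                              denoise_channels = c("both", "t2w"),
                              volume_after_reseg = FALSE,
                              merge_matrices = FALSE) {
  denoise_channels <- match.arg(denoise_channels)
  stopifnot(sigma_mm >= 0, iso_spacing_mm > 0,
            reseg_lo_pct >= 0, reseg_lo_pct < reseg_hi_pct,
            reseg_hi_pct <= 100,
            n_bins_intensity >= 2, n_bins_texture >= 2)
  structure(list(sigma_mm = sigma_mm, iso_spacing_mm = iso_spacing_mm,
                 reseg_lo_pct = reseg_lo_pct, reseg_hi_pct = reseg_hi_pct,
                 n_bins_intensity = as.integer(n_bins_intensity),
                 n_bins_texture = as.integer(n_bins_texture),
                 denoise_channels = denoise_channels,
                 volume_after_reseg = isTRUE(volume_after_reseg),
                 merge_matrices = isTRUE(merge_matrices)),
            class = "preprocess_config")
}

# sampled, normalized 1D Gaussian kernel; radius covers 4 sigma (min 1)
gauss_kernel_1d <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# reflect out-of-range 1-based indices back into 1..n (mirror about edges,
# edge voxel not repeated: ... 3 2 | 1 2 3 ... n | n-1 n-2 ...)
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  m <- 2L * n - 2L
  j <- (i - 1L) %% m
  j <- ifelse(j < 0L, j + m, j)
  as.integer(ifelse(j >= n, m - j, j) + 1L)
}

# convolve a 3D array with a 1D kernel along one axis, reflective boundaries
conv_axis <- function(a, kern, axis) {
  d <- dim(a)
  n <- d[axis]
  r <- (length(kern) - 1L) %/% 2L
  out <- array(0, dim = d)
  for (t in seq_along(kern)) {
    off <- t - r - 1L
    idx <- reflect_index(seq_len(n) + off, n)
    shifted <- switch(axis,
                      a[idx, , , drop = FALSE],
                      a[, idx, , drop = FALSE],
                      a[, , idx, drop = FALSE])
    out <- out + kern[t] * shifted
  }
  out
}

#' Gaussian de-noising of a volume
#'
#' Convolves the volume with an isotropic Gaussian of physical width
#' `sigma_mm`, converted to voxel units per axis by dividing by the voxel
#' spacing. Boundaries are handled by reflection. `sigma_mm = 0` returns the
#' input unchanged.
#'
#' @param vol a [volume3d()].
#' @param sigma_mm Gaussian sigma in mm, >= 0.
#' @return The filtered [volume3d()] on the same grid.
#' @export
denoise_gaussian <- function(vol, sigma_mm = 0.5) {
  stopifnot(inherits(vol, "volume3d"), sigma_mm >= 0)
  if (sigma_mm == 0) return(vol)
  a <- vol$data
  for (axis in 1:3) {
    sig_vox <- sigma_mm / vol$spacing[axis]
    a <- conv_axis(a, gauss_kernel_1d(sig_vox), axis)
  }
  volume3d(a, vol$spacing, vol$origin)
}

# 1D interpolation weight matrix mapping n source samples (spacing s) to m
# target samples (spacing t), shared origin, voxel centers at index*spacing
interp_weights_1d <- function(n, s, t, m, method) {
  v <- (seq_len(m) - 1) * t / s          # fractional source coordinate, 0-based
  v <- pmin(pmax(v, 0), n - 1)
  W <- matrix(0, nrow = m, ncol = n)
  if (method == "nearest" || n == 1L) {
    j <- pmin(pmax(round(v), 0), n - 1)
    W[cbind(seq_len(m), j + 1)] <- 1
  } else {
    j0 <- pmin(floor(v), n - 2)
    f <- v - j0
    W[cbind(seq_len(m), j0 + 1)] <- W[cbind(seq_len(m), j0 + 1)] + (1 - f)
    W[cbind(seq_len(m), j0 + 2)] <- W[cbind(seq_len(m), j0 + 2)] + f
  }
  W
}

apply_axis_matrix <- function(a, W, axis) {
  d <- dim(a)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  res <- W %*% matrix(ap, nrow = dp[1])
  dim(res) <- c(nrow(W), dp[2], dp[3])
  aperm(res, order(perm))
}

#' Resample a volume or mask to isotropic spacing
#'
#' Trilinear interpolation for images, nearest neighbour for masks (so mask
#' outputs stay binary). The output grid shares the input origin; the number
#' of voxels per axis is `round(n * spacing / target)`, preserving the
#' physical extent to within one voxel. A single-voxel axis falls back to
#' nearest-neighbour sampling along that axis.
#'
#' @param vol a [volume3d()] or [mask3d()].
#' @param target_mm target isotropic spacing in mm.
#' @param method `"trilinear"` or `"nearest"`; defaults to `"nearest"` for
#'   masks and `"trilinear"` otherwise.
#' @return The resampled object, same class as the input.
#' @export
resample_isotropic <- function(vol, target_mm = 0.5,
                               method = if (inherits(vol, "mask3d"))
                                 "nearest" else "trilinear") {
  stopifnot(inherits(vol, "volume3d"), target_mm > 0)
  method <- match.arg(method, c("trilinear", "nearest"))
  d <- dim(vol$data)
  a <- vol$data
  storage.mode(a) <- "double"
  for (axis in 1:3) {
    s <- vol$spacing[axis]
    m <- max(1L, as.integer(round(d[axis] * s / target_mm)))
    W <- interp_weights_1d(d[axis], s, target_mm, m, method)
    a <- apply_axis_matrix(a, W, axis)
  }
  if (inherits(vol, "mask3d")) {
    mask3d(array(as.integer(round(a)), dim = dim(a)),
           spacing = rep(target_mm, 3), origin = vol$origin)
  } else {
    volume3d(a, spacing = rep(target_mm, 3), origin = vol$origin)
  }
}

#' Re-segment an ROI between intensity percentiles
#'
#' Retains only mask voxels whose intensity lies within the closed interval
#' `[P_lo, P_hi]` of the in-mask intensity distribution, removing outlier
#' voxels before discretization. Percentiles use linear interpolation between
#' order statistics. The operation is idempotent in the trivial sense of
#' re-application on its own output shrinking no further when the percentile
#' band already covers the retained values.
#'
#' @param vol intensity [volume3d()] on the mask grid.
#' @param mask a nonempty [mask3d()].
#' @param lo_pct,hi_pct percentile bounds in `[0, 100]`.
#' @return The re-segmented [mask3d()].
#' @export
resegment_roi <- function(vol, mask, lo_pct = 1, hi_pct = 99) {
  stopifnot(inherits(vol, "volume3d"), inherits(mask, "mask3d"),
            lo_pct >= 0, lo_pct < hi_pct, hi_pct <= 100)
  inm <- mask$data == 1L
  if (!any(inm)) stop("mask is empty")
  vals <- vol$data[inm]
  qs <- stats::quantile(vals, c(lo_pct, hi_pct) / 100, names = FALSE, type = 7)
  keep <- inm & vol$data >= qs[1] & vol$data <= qs[2]
  if (!any(keep)) stop("re-segmentation removed all voxels")
  mask3d(array(as.integer(keep), dim = dim(mask$data)),
         spacing = mask$spacing, origin = mask$origin)
}

#' Fixed-bin-number discretization of an ROI
#'
#' Maps in-mask intensities to integer grey levels `1..n_bins` spanning the
#' in-mask min-max range:
#' `level = min(n_bins, 1 + floor(n_bins * (x - min) / (max - min)))`.
#' A constant ROI maps every voxel to level 1. Voxels outside the mask get
#' level 0. FBN discretization is invariant to positive affine rescaling of
#' the intensities.
#'
#' @param vol intensity [volume3d()].
#' @param mask nonempty [mask3d()] on the same grid.
#' @param n_bins number of grey levels.
#' @return A `discretized_roi`: list with `levels` (integer array), `n_bins`,
#'   `mask`, `spacing`.
#' @export
discretize_fbn <- function(vol, mask, n_bins) {
  stopifnot(inherits(vol, "volume3d"), inherits(mask, "mask3d"), n_bins >= 2)
  inm <- mask$data == 1L
  if (!any(inm)) stop("mask is empty")
  vals <- vol$data[inm]
  mn <- min(vals); mx <- max(vals)
  lev <- array(0L, dim = dim(vol$data))
  if (mx > mn) {
    lev[inm] <- pmin(as.integer(n_bins),
                     1L + as.integer(floor(n_bins * (vals - mn) / (mx - mn))))
  } else {
    lev[inm] <- 1L
  }
  structure(list(levels = lev, n_bins = as.integer(n_bins), mask = mask,
                 spacing = vol$spacing),
            class = "discretized_roi")
}
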