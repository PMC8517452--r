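#' Candidate-detection configuration
#'
#' Thresholds of the rule-based lesion-candidate filter. A voxel survives iff
#' its malignancy probability, ADC value and first-minute contrast uptake all
#' pass; connected survivors form candidates kept only when large enough.
#' Defaults: probability >= 0.60, ADC within 200-1600 (1e-6 mm^2/s), uptake
#' >= 100 percent, maximal axial cross-sectional area > 100 mm^2. All voxel
#' thresholds are inclusive on the keep side; the area threshold is strict.
#'
#' @param prob_min minimum malignancy probability.
#' @param adc_min,adc_max ADC band in 1e-6 mm^2/s.
#' @param uptake_min minimum percent maximum uptake in the first minute.
#' @param min_area_mm2 candidate area threshold (strictly exceeded).
#' @param area_mode `"axial"` (largest per-slice cross-section, default) or
#'   `"volume"` (total volume in mm^3 compared against the same threshold).
#' @param connectivity 26 (default) or 6 for 3D component labeling.
#' @return A `detection_config` list.
#' @export
detection_config <- function(prob_min = 0.60, adc_min = 200, adc_max = 1600,
                             uptake_min = 100, min_area_mm2 = 100,
                             area_mode = c("axial", "volume"),
                             connectivity = 26L) {
  area_mode <- match.arg(area_mode)
  stopifnot(prob_min >= 0, prob_min <= 1, adc_min < adc_max,
            min_area_mm2 > 0, connectivity %in% c(6L, 26L))
  structure(list(prob_min = prob_min, adc_min = adc_min, adc_max = adc_max,
                 adc_units = "1e-6 mm^2/s",
                 uptake_min = uptake_min, min_area_mm2 = min_area_mm2,
                 area_mode = area_mode, connectivity = as.integer(connectivity)),
            class = "detection_config")
}

#' Voxel-level candidate filtering
#'
#' Keeps a voxel iff `prob >= prob_min` AND `adc_min <= adc <= adc_max` AND
#' `uptake >= uptake_min` — the conjunction of the three discard rules, with
#' inclusive keep-side boundaries. Monotone: relaxing any threshold never
#' removes a kept voxel.
#'
#' @param bundle validated [case_bundle()] with `prob`, `adc`, `uptake`.
#' @param cfg a [detection_config()].
#' @return A [mask3d()] of surviving voxels.
#' @export
filter_voxels <- function(bundle, cfg = detection_config()) {
  stopifnot(inherits(bundle, "case_bundle"))
  validate_bundle(bundle)
  keep <- bundle$prob$data >= cfg$prob_min &
    bundle$adc$data >= cfg$adc_min & bundle$adc$data <= cfg$adc_max &
    bundle$uptake$data >= cfg$uptake_min
  mask3d(array(as.integer(keep), dim = dim(bundle$prob$data)),
         spacing = bundle$prob$spacing, origin = bundle$prob$origin)
}

# offsets of the 6- or 26-neighbourhood
neighbour_offsets <- function(connectivity) {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o <- o[rowSums(abs(o)) > 0, , drop = FALSE]
  if (connectivity == 6L) o <- o[rowSums(abs(o)) == 1, , drop = FALSE]
  o
}

# label connected components of a binary array by frontier-expanding BFS
label_components <- function(bin, connectivity = 26L) {
  d <- dim(bin)
  lab <- array(0L, dim = d)
  offs <- neighbour_offsets(connectivity)
  seeds <- which(bin == 1L)
  nlab <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    nlab <- nlab + 1L
    lab[s] <- nlab
    frontier <- s
    while (length(frontier)) {
      ai <- arrayInd(frontier, d)
      nxt <- integer(0)
      for (r in seq_len(nrow(offs))) {
        nb <- ai + matrix(offs[r, ], nrow(ai), 3, byrow = TRUE)
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] +
          (nb[ok, 3] - 1L) * d[1] * d[2]
        lin <- lin[bin[lin] == 1L & lab[lin] == 0L]
        if (length(lin)) {
          lab[lin] <- nlab
          nxt <- c(nxt, lin)
        }
      }
      frontier <- unique(nxt)
    }
  }
  list(labels = lab, n = nlab)
}

#' Extract candidate lesions from a filtered voxel mask
#'
#' Labels 3D connected components of the kept-voxel mask (26-connectivity by
#' default) and emits each component whose maximal axial cross-sectional area
#' strictly exceeds `min_area_mm2` (or whose volume exceeds it, in
#' `area_mode = "volume"`). Candidates are sorted by descending volume.
#'
#' @param kept binary [mask3d()] from [filter_voxels()].
#' @param cfg a [detection_config()].
#' @return List of `candidate_region` objects, each with `voxel_indices`
#'   (linear indices into the grid), `max_axial_area_mm2`, `volume_mm3`,
#'   `centroid` (physical mm), `label`.
#' @export
extract_candidates <- function(kept, cfg = detection_config()) {
  stopifnot(inherits(kept, "mask3d"))
  lb <- label_components(kept$data, cfg$connectivity)
  if (lb$n == 0L) return(list())
  sp <- kept$spacing
  vox_area <- sp[1] * sp[2]
  vox_vol <- prod(sp)
  d <- dim(kept$data)
  out <- list()
  for (k in seq_len(lb$n)) {
    idx <- which(lb$labels == k)
    ai <- arrayInd(idx, d)
    slice_counts <- table(ai[, 3])
    max_area <- max(slice_counts) * vox_area
    vol <- length(idx) * vox_vol
    size_meas <- if (cfg$area_mode == "axial") max_area else vol
    if (size_meas > cfg$min_area_mm2) {
      centroid <- kept$origin + (colMeans(ai) - 1) * sp
      out[[length(out) + 1L]] <- structure(
        list(voxel_indices = idx, max_axial_area_mm2 = max_area,
             volume_mm3 = vol, centroid = centroid, label = k),
        class = "candidate_region")
    }
  }
  if (length(out) > 1L)
    out <- out[order(vapply(out, `[[`, numeric(1), "volume_mm3"),
                     decreasing = TRUE)]
  out
}

#' @export
print.candidate_region <- function(x, ...) {
  cat(sprintf(paste0("<candidate_region> %d voxels, volume %.1f mm^3, ",
                     "max axial area %.1f mm^2\n"),
              length(x$voxel_indices), x$volume_mm3, x$max_axial_area_mm2))
  invisible(x)
}

#' Dice overlap between two masks (or a candidate and a mask)
#'
#' @param a,b [mask3d()] objects on the same grid, or `a` a
#'   `candidate_region` on `b`'s grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_overlap <- function(a, b) {
  ai <- if (inherits(a, "candidate_region")) a$voxel_indices else
    which(a$data == 1L)
  bi <- which(b$data == 1L)
  if (length(ai) + length(bi) == 0L) return(NaN)
  2 * length(intersect(ai, bi)) / (length(ai) + length(bi))
}

#' Select the candidate matching a reference lesion
#'
#' Automated surrogate for the radiologist's lesion confirmation: returns the
#' candidate with maximal Dice overlap against the reference mask.
#'
#' @param candidates list from [extract_candidates()].
#' @param reference nonempty [mask3d()] on the same grid.
#' @return The best-matching `candidate_region`, with its Dice attached as
#'   attribute `"dice"`; `NULL` if the candidate list is empty.
#' @export
select_lesion <- function(candidates, reference) {
  stopifnot(inherits(reference, "mask3d"))
  if (mask_count(reference) == 0L) stop("reference mask is empty")
  if (length(candidates) == 0L) return(NULL)
  dc <- vapply(candidates, dice_overlap, numeric(1), b = reference)
  best <- which.max(dc)
  structure(candidates[[best]], dice = dc[best])
}

#' Convert a candidate to a mask on its source grid
#'
#' @param cand a `candidate_region`.
#' @param grid a [volume3d()] or [mask3d()] giving the grid geometry.
#' @return A [mask3d()].
#' @export
candidate_mask <- function(cand, grid) {
  m <- array(0L, dim = dim(grid$data))
  m[cand$voxel_indices] <- 1L
  mask3d(m, grid$spacing, grid$origin)
}

#' Summarize candidates as a data.frame
#'
#' @param candidates list from [extract_candidates()].
#' @return data.frame with id, volume_mm3, max_axial_area_mm2 and centroid.
#' @export
candidate_summary <- function(candidates) {
  if (length(candidates) == 0L)
    return(data.frame(id = integer(0), volume_mm3 = numeric(0),
                      max_axial_area_mm2 = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), centroid_z = numeric(0)))
  data.frame(
    id = seq_along(candidates),
    volume_mm3 = vapply(candidates, `[[`, numeric(1), "volume_mm3"),
    max_axial_area_mm2 = vapply(candidates, `[[`, numeric(1),
                                "max_axial_area_mm2"),
    centroid_x = vapply(candidates, function(c) c$centroid[1], numeric(1)),
    centroid_y = vapply(candidates, function(c) c$centroid[2], numeric(1)),
    centroid_z = vapply(candidates, function(c) c$centroid[3], numeric(1)))
}
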