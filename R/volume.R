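#' Construct a 3D scalar volume
#'
#' A `volume3d` is the package's carrier for one co-registered mpMRI channel:
#' a 3D array of voxel values plus the geometric metadata needed to move
#' between voxel indices and physical (scanner) coordinates. Voxel indexing is
#' 0-based `(x, y, z)` with `z` the axial slice index; the physical position of
#' voxel `(i, j, k)` is `origin + c(i, j, k) * spacing`.
#'
#' @param data numeric 3D array of voxel values. Intensities are in arbitrary
#'   units for T2w and in 1e-6 mm^2/s for ADC maps.
#' @param spacing numeric length-3, voxel size in mm along x, y, z; all
#'   strictly positive.
#' @param origin numeric length-3, physical position (mm) of voxel (0,0,0).
#' @return An object of class `volume3d` with fields `data`, `spacing`,
#'   `origin`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D volume: 'data' must be a 3-dimensional array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values (mm)")
  if (any(dim(data) < 1L)) stop("grid dimensions must be >= 1 in each axis")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' Construct a binary 3D mask on a volume grid
#'
#' @param data 3D array with values in {0, 1} (logical arrays are accepted).
#' @inheritParams volume3d
#' @return An object of class `mask3d` (also inheriting `volume3d`).
#' @export
mask3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.logical(data)) {
    d <- array(as.integer(data), dim = dim(data))
  } else {
    d <- data
  }
  v <- volume3d(d, spacing, origin)
  if (!all(v$data %in% c(0, 1)))
    stop("mask values must all be 0 or 1")
  storage.mode(v$data) <- "integer"
  class(v) <- c("mask3d", "volume3d")
  v
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin (%s) mm\n",
              class(x)[1L], paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  rng <- range(x$data)
  cat(sprintf("  value range [%g, %g]\n", rng[1L], rng[2L]))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' Number of foreground voxels in a mask
#' @param mask a [mask3d()].
#' @return integer count of voxels equal to 1.
#' @export
mask_count <- function(mask) sum(mask$data == 1L)

voxel_volume_mm3 <- function(x) prod(x$spacing)

#' Read a 3D volume from a NIfTI-1 file
#'
#' Reads the image with its voxel spacing and origin. Only axis-aligned grids
#' are accepted: oblique direction cosines are rejected rather than silently
#' reoriented, because the pipeline assumes pre-registered axial stacks.
#' No resampling is performed.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param mask logical; if `TRUE` return a [mask3d()] (values checked binary).
#' @return A [volume3d()] or [mask3d()].
#' @export
load_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable image header in ", path,
                                           ": ", conditionMessage(e)))
  if (length(dim(img)) != 3L)
    stop("expected 3D volume, got ", length(dim(img)), "D image: ", path)
  sp <- as.numeric(RNifti::pixdim(img))
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-6 * max(abs(diag(rot)), 1)))
    stop("non-axis-aligned orientation in ", path,
         "; reorient to an axial grid before loading")
  dat <- array(as.numeric(img), dim = dim(img))
  org <- as.numeric(aff[1:3, 4])
  if (mask) {
    if (!all(dat %in% c(0, 1))) stop("mask file contains non-binary values: ", path)
    mask3d(dat, spacing = sp, origin = org)
  } else {
    volume3d(dat, spacing = sp, origin = org)
  }
}

#' Write a volume or mask to a NIfTI-1 file
#'
#' Masks are stored as unsigned 8-bit; images as 32-bit float. The affine is
#' the axis-aligned diagonal of the spacing with the origin as translation.
#'
#' @param vol a [volume3d()] or [mask3d()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  img <- RNifti::asNifti(vol$data, reference = list(
    pixdim = c(1, vol$spacing, 0, 0, 0, 0),
    qform_code = 0L, sform_code = 2L,
    srow_x = aff[1, ], srow_y = aff[2, ], srow_z = aff[3, ]))
  dt <- if (inherits(vol, "mask3d")) "uint8" else "double"
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Bundle the co-registered channels of one case
#'
#' @param t2w,adc,uptake,prob [volume3d()] channels: T2-weighted intensity,
#'   ADC map (1e-6 mm^2/s), percent maximum contrast uptake in the first
#'   minute, and voxel-wise malignancy probability in `[0, 1]`.
#' @param mask optional [mask3d()] lesion mask on the same grid.
#' @return An object of class `case_bundle`.
#' @export
case_bundle <- function(t2w, adc, uptake, prob, mask = NULL) {
  b <- structure(list(t2w = t2w, adc = adc, uptake = uptake, prob = prob,
                      mask = mask), class = "case_bundle")
  b
}

#' Check geometric consistency of a case bundle
#'
#' All channels (and the mask, if present) must share grid dimensions,
#' spacing and origin to within 1e-3 mm. Returns the bundle unchanged if the
#' geometry matches; the data are never mutated.
#'
#' @param bundle a [case_bundle()].
#' @param tol_mm tolerance in mm for spacing/origin comparison.
#' @return The validated bundle, invisibly identical to the input.
#' @export
validate_bundle <- function(bundle, tol_mm = 1e-3) {
  stopifnot(inherits(bundle, "case_bundle"))
  chans <- c("t2w", "adc", "uptake", "prob")
  if (!is.null(bundle$mask)) chans <- c(chans, "mask")
  ref <- bundle$t2w
  for (ch in chans) {
    v <- bundle[[ch]]
    if (is.null(v)) stop("bundle channel missing: ", ch)
    if (!identical(dim(v$data), dim(ref$data)))
      stop("geometry error in channel '", ch, "': dimensions ",
           paste(dim(v$data), collapse = "x"), " differ from t2w ",
           paste(dim(ref$data), collapse = "x"))
    if (any(abs(v$spacing - ref$spacing) > tol_mm))
      stop("geometry error in channel '", ch, "': spacing (",
           paste(format(v$spacing), collapse = ", "),
           ") differs from t2w beyond ", tol_mm, " mm")
    if (any(abs(v$origin - ref$origin) > tol_mm))
      stop("geometry error in channel '", ch, "': origin differs from t2w",
           " beyond ", tol_mm, " mm")
  }
  pr <- range(bundle$prob$data)
  if (pr[1] < -1e-9 || pr[2] > 1 + 1e-9)
    stop("geometry error in channel 'prob': probabilities outside [0, 1]")
  invisible(bundle)
}

#' @export
print.case_bundle <- function(x, ...) {
  cat("<case_bundle>\n")
  for (ch in c("t2w", "adc", "uptake", "prob"))
    cat(sprintf("  %-6s %s\n", ch, paste(dim(x[[ch]]$data), collapse = "x")))
  if (!is.null(x$mask))
    cat(sprintf("  mask   %d foreground voxels\n", mask_count(x$mask)))
  invisible(x)
}
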