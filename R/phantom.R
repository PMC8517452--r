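# zero-mean, unit-variance Gaussian random field with a physical correlation
# length, obtained by smoothing white noise (uses the caller's RNG state)
grf <- function(dimv, spacing, corr_len_mm) {
  w <- array(stats::rnorm(prod(dimv)), dim = dimv)
  if (corr_len_mm > 0) {
    v <- denoise_gaussian(volume3d(w, spacing), corr_len_mm)
    w <- v$data
  }
  (w - mean(w)) / stats::sd(w)
}

#' Phantom specification
#'
#' Parameters of the synthetic mpMRI generator. Two lesion classes emulate
#' low-aggressive (GG <= 2) and high-aggressive (GG > 2) prostate cancers as
#' generative populations differing in volume, ADC level and texture
#' regularity: the high-aggressive class has lower ADC (the ADC-grade
#' inverse relation, imposed as a simulation assumption), larger volumes and
#' a shorter texture correlation length (more heterogeneous). All defaults
#' are in physical units; ADC in 1e-6 mm^2/s, volumes in ml, lengths in mm.
#'
#' @param grid_shape integer length-3 grid dimensions.
#' @param spacing voxel spacing in mm (anisotropic, axial slices thicker).
#' @param n_lesions lesions per case.
#' @param low,high per-class parameter lists: `vol_ml` (volume range),
#'   `adc_mean`, `adc_between_sd` (between-lesion ADC spread), `t2w_mean`,
#'   `corr_len_mm` (texture correlation length).
#' @param adc_field_sd,t2w_field_sd within-lesion texture amplitude.
#' @param background list: `adc_mean`, `adc_field_sd`, `t2w_mean`,
#'   `t2w_field_sd`, `uptake_mean`, `uptake_field_sd`, `prob_mean`,
#'   `corr_len_mm`.
#' @param noise_sd list: white-noise sd for `adc` and `t2w`.
#' @param prob_plateau minimum malignancy probability inside lesions.
#' @param uptake_plateau minimum percent uptake inside lesions.
#' @param prevalence probability a lesion is high-aggressive when `classes`
#'   is not given to [simulate_phantom()].
#' @param seed integer seed; the generator is fully determined by it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(72L, 72L, 28L),
                         spacing = c(0.6, 0.6, 1.2),
                         n_lesions = 1L,
                         low = list(vol_ml = c(0.5, 1.2), adc_mean = 1100,
                                    adc_between_sd = 60, t2w_mean = 320,
                                    corr_len_mm = 2.5),
                         high = list(vol_ml = c(0.9, 2.0), adc_mean = 850,
                                     adc_between_sd = 60, t2w_mean = 260,
                                     corr_len_mm = 1.2),
                         adc_field_sd = 120, t2w_field_sd = 45,
                         background = list(adc_mean = 1600, adc_field_sd = 100,
                                           t2w_mean = 400, t2w_field_sd = 60,
                                           uptake_mean = 60,
                                           uptake_field_sd = 20,
                                           prob_mean = 0.15,
                                           corr_len_mm = 3),
                         noise_sd = list(adc = 30, t2w = 15),
                         prob_plateau = 0.8, uptake_plateau = 130,
                         prevalence = 0.5, seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            all(spacing > 0), n_lesions >= 1L,
            high$adc_mean < low$adc_mean,
            prevalence > 0, prevalence < 1)
  structure(list(grid_shape = as.integer(grid_shape), spacing = spacing,
                 n_lesions = as.integer(n_lesions), low = low, high = high,
                 adc_field_sd = adc_field_sd, t2w_field_sd = t2w_field_sd,
                 background = background, noise_sd = noise_sd,
                 prob_plateau = prob_plateau, uptake_plateau = uptake_plateau,
                 prevalence = prevalence, seed = as.integer(seed)),
            class = "phantom_spec")
}

# carve one lesion mask of exactly `n_target` voxels: an ellipsoidal distance
# field perturbed by smooth noise, thresholded at the n-th smallest value.
# Lesions extend in-plane and are flattened through-plane (volume preserved),
# the way prostate lesions present on thick-slice axial acquisitions.
carve_lesion <- function(dimv, spacing, center_vox, n_target, corr_len_mm) {
  r_mm <- (3 * n_target * prod(spacing) / (4 * pi))^(1 / 3)
  inplane <- stats::runif(1, 1.25, 1.6)
  u <- stats::runif(2, 0.9, 1.1)
  ax <- r_mm * c(inplane * u[1], inplane * u[2],
                 1 / (inplane^2 * u[1] * u[2]))
  cx <- lapply(1:3, function(a) ((seq_len(dimv[a]) - center_vox[a]) *
                                   spacing[a]))
  D <- outer(outer((cx[[1]] / ax[1])^2, (cx[[2]] / ax[2])^2, "+"),
             (cx[[3]] / ax[3])^2, "+")
  P <- grf(dimv, spacing, corr_len_mm = max(corr_len_mm, 1))
  f <- D + 0.25 * P
  thr <- sort(as.vector(f), partial = n_target)[n_target]
  f <= thr
}

#' Simulate a synthetic mpMRI case
#'
#' Generates a seeded case bundle with an ellipsoidal gland, planted lesions
#' (smoothed random blobs of exactly the drawn target volume), and four
#' mutually consistent channels: ADC and T2w as class mean plus a Gaussian
#' random field with class-specific correlation length plus white noise, a
#' probability map at or above the plateau inside lesions and low outside,
#' and an uptake map likewise. Overlapping lesion placements are re-drawn
#' (up to 100 attempts).
#'
#' @param spec a [phantom_spec()].
#' @param classes optional integer vector (length `n_lesions`, 1 = high
#'   aggressive) fixing the lesion classes; otherwise drawn with
#'   `spec$prevalence`.
#' @return List with `bundle` ([case_bundle()]), `masks` (list of truth
#'   [mask3d()], one per lesion), `labels` (1 = high aggressive), `spec`.
#' @export
simulate_phantom <- function(spec = phantom_spec(), classes = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    dm <- spec$grid_shape
    sp <- spec$spacing
    bg <- spec$background
    vox_vol <- prod(sp)

    if (is.null(classes))
      classes <- stats::rbinom(spec$n_lesions, 1L, spec$prevalence)
    stopifnot(length(classes) == spec$n_lesions)

    # gland: centered ellipsoid covering ~40% of the FOV extent
    ext <- dm * sp
    gax <- ext * c(0.42, 0.38, 0.40) / 2
    ctr <- (dm + 1) / 2
    cx <- lapply(1:3, function(a) (seq_len(dm[a]) - ctr[a]) * sp[a])
    G <- outer(outer((cx[[1]] / gax[1])^2, (cx[[2]] / gax[2])^2, "+"),
               (cx[[3]] / gax[3])^2, "+") <= 1

    lesion_masks <- list()
    occupied <- array(FALSE, dim = dm)
    for (li in seq_len(spec$n_lesions)) {
      cls <- if (classes[li] == 1L) spec$high else spec$low
      n_target <- as.integer(round(stats::runif(1, cls$vol_ml[1],
                                                cls$vol_ml[2]) * 1000 /
                                     vox_vol))
      placed <- FALSE
      for (att in 1:100) {
        cen <- ctr + stats::runif(3, -0.5, 0.5) * gax * 0.9 / sp
        les <- carve_lesion(dm, sp, cen, n_target, cls$corr_len_mm)
        if (!any(les & occupied) && all(which(les, arr.ind = TRUE) > 1) &&
            all(sweep(which(les, arr.ind = TRUE), 2, dm - 1L) <= 0)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place lesion ", li,
                        " without overlap after 100 attempts")
      occupied <- occupied | les
      lesion_masks[[li]] <- mask3d(array(as.integer(les), dim = dm),
                                   spacing = sp)
    }

    adc <- bg$adc_mean + bg$adc_field_sd * grf(dm, sp, bg$corr_len_mm) +
      stats::rnorm(prod(dm), sd = spec$noise_sd$adc)
    t2w <- bg$t2w_mean + bg$t2w_field_sd * grf(dm, sp, bg$corr_len_mm) +
      stats::rnorm(prod(dm), sd = spec$noise_sd$t2w)
    uptake <- bg$uptake_mean + bg$uptake_field_sd * grf(dm, sp, bg$corr_len_mm)
    prob <- pmin(pmax(bg$prob_mean + 0.10 * grf(dm, sp, bg$corr_len_mm), 0),
                 0.45)
    dim(adc) <- dim(t2w) <- dim(uptake) <- dim(prob) <- dm

    for (li in seq_len(spec$n_lesions)) {
      cls <- if (classes[li] == 1L) spec$high else spec$low
      les <- lesion_masks[[li]]$data == 1L
      tex_adc <- grf(dm, sp, cls$corr_len_mm)
      tex_t2w <- grf(dm, sp, cls$corr_len_mm)
      lesion_adc <- cls$adc_mean + stats::rnorm(1, sd = cls$adc_between_sd)
      adc[les] <- lesion_adc + spec$adc_field_sd * tex_adc[les] +
        stats::rnorm(sum(les), sd = spec$noise_sd$adc)
      t2w[les] <- cls$t2w_mean + spec$t2w_field_sd * tex_t2w[les] +
        stats::rnorm(sum(les), sd = spec$noise_sd$t2w)
      uptake[les] <- spec$uptake_plateau +
        abs(30 * tex_t2w[les] + stats::rnorm(sum(les), sd = 10))
      prob[les] <- spec$prob_plateau +
        (1 - spec$prob_plateau) * stats::runif(sum(les))
    }
    adc <- pmax(adc, 0); dim(adc) <- dm
    t2w <- pmax(t2w, 0); dim(t2w) <- dm

    bundle <- case_bundle(t2w = volume3d(t2w, sp), adc = volume3d(adc, sp),
                          uptake = volume3d(uptake, sp),
                          prob = volume3d(prob, sp))
    validate_bundle(bundle)
    list(bundle = bundle, masks = lesion_masks,
         labels = as.integer(classes), spec = spec)
  })
}

#' Simulate a cohort of single-lesion cases
#'
#' Convenience wrapper generating `n_cases` phantoms with balanced,
#' alternating class labels and per-case seeds derived from `seed`.
#'
#' @param n_cases number of cases.
#' @param spec base [phantom_spec()] (its `n_lesions` is forced to 1).
#' @param seed integer master seed.
#' @return List of [simulate_phantom()] results; labels alternate 0, 1, ...
#' @export
simulate_cohort <- function(n_cases, spec = phantom_spec(), seed = 1L) {
  lapply(seq_len(n_cases), function(i) {
    sp <- spec
    sp$n_lesions <- 1L
    sp$seed <- as.integer((seed + 7919 * i) %% .Machine$integer.max)
    simulate_phantom(sp, classes = (i + 1L) %% 2L)
  })
}

#' Feature-table specification
#'
#' @param n_rows lesions.
#' @param n_features feature columns (default 92).
#' @param informative indices of class-informative columns.
#' @param delta_mu class-1 mean shift of informative columns, in sd units.
#' @param corr_blocks list of `list(cols = indices, rho = value)` blocks of
#'   equicorrelated columns (to exercise correlation pruning).
#' @param prevalence fraction of class-1 rows.
#' @param seed integer seed.
#' @return A `table_spec` list.
#' @export
table_spec <- function(n_rows = 200L, n_features = 92L,
                       informative = 1:3, delta_mu = 2,
                       corr_blocks = list(), prevalence = 0.5, seed = 1L) {
  stopifnot(n_rows >= 4L, n_features >= 1L, length(informative) >= 1L,
            all(informative <= n_features), prevalence > 0, prevalence < 1)
  structure(list(n_rows = as.integer(n_rows),
                 n_features = as.integer(n_features),
                 informative = as.integer(informative), delta_mu = delta_mu,
                 corr_blocks = corr_blocks, prevalence = prevalence,
                 seed = as.integer(seed)), class = "table_spec")
}

#' Simulate a lesion feature table with known structure
#'
#' Multivariate Gaussian features (unit variance) with optional
#' equicorrelated blocks; informative columns are shifted by
#' `delta_mu` standard deviations in the class-1 rows. Fully seeded.
#'
#' @param spec a [table_spec()].
#' @return A [feature_table()] with columns `f1..fp`.
#' @export
simulate_feature_table <- function(spec = table_spec()) {
  stopifnot(inherits(spec, "table_spec"))
  with_seed(spec$seed, {
    n <- spec$n_rows; p <- spec$n_features
    n1 <- round(n * spec$prevalence)
    labels <- sample(c(rep(1L, n1), rep(0L, n - n1)))
    Sigma <- diag(p)
    for (b in spec$corr_blocks) {
      Sigma[b$cols, b$cols] <- b$rho
      diag(Sigma)[b$cols] <- 1
    }
    L <- chol(Sigma)
    x <- matrix(stats::rnorm(n * p), n, p) %*% L
    x[labels == 1L, spec$informative] <-
      x[labels == 1L, spec$informative] + spec$delta_mu
    colnames(x) <- paste0("f", seq_len(p))
    feature_table(x, labels)
  })
}
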