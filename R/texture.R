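#' The 13 unique direction offsets of a 3D image
#'
#' Texture matrices in 3D are computed along the 13 non-antiparallel offsets
#' of the 26-neighbourhood (Chebyshev distance 1); together with their
#' negations they cover all 26 nonzero offsets with components in
#' \{-1, 0, 1\}. Canonical order: ascending in (dz, dy, dx) among the offsets
#' whose first nonzero component (scanning dz, then dy, then dx) is positive.
#'
#' @return A 13 x 3 integer matrix; columns are dx, dy, dz.
#' @export
direction_offsets_3d <- function() {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  keep <- offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
    (offs$dz == 0 & offs$dy == 0 & offs$dx > 0)
  offs <- offs[keep, ]
  offs <- offs[order(offs$dz, offs$dy, offs$dx), ]
  m <- as.matrix(offs)
  dimnames(m) <- list(NULL, c("dx", "dy", "dz"))
  storage.mode(m) <- "integer"
  m
}

#' Grey-level co-occurrence matrix for one direction
#'
#' Counts co-occurrences of grey levels between in-mask voxel pairs separated
#' by `offset * distance` (both voxels in the mask), symmetrized (each pair
#' counted in both orders) and normalized to sum 1.
#'
#' @param roi a `discretized_roi` from [discretize_fbn()].
#' @param offset integer length-3 offset (dx, dy, dz).
#' @param distance inter-voxel distance in voxel units (>= 1).
#' @return List of class `texture_matrix`: `kind = "GLCM"`, `matrix`
#'   (`n_bins` x `n_bins`, sums to 1 unless empty), `offset`, `n_bins`,
#'   `n_pairs` (symmetrized count), `empty` flag.
#' @export
glcm_matrix <- function(roi, offset, distance = 1L) {
  stopifnot(inherits(roi, "discretized_roi"), length(offset) == 3,
            distance >= 1)
  lev <- roi$levels
  d <- dim(lev)
  o <- as.integer(offset) * as.integer(distance)
  rng <- vector("list", 3)
  for (ax in 1:3) {
    lo <- max(1L, 1L - o[ax]); hi <- min(d[ax], d[ax] - o[ax])
    if (lo > hi) {
      return(structure(list(kind = "GLCM",
                            matrix = matrix(0, roi$n_bins, roi$n_bins),
                            offset = as.integer(offset), n_bins = roi$n_bins,
                            n_pairs = 0L, empty = TRUE),
                       class = "texture_matrix"))
    }
    rng[[ax]] <- lo:hi
  }
  a <- lev[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  b <- lev[rng[[1]] + o[1], rng[[2]] + o[2], rng[[3]] + o[3], drop = FALSE]
  sel <- a > 0L & b > 0L
  nb <- roi$n_bins
  if (!any(sel)) {
    return(structure(list(kind = "GLCM", matrix = matrix(0, nb, nb),
                          offset = as.integer(offset), n_bins = nb,
                          n_pairs = 0L, empty = TRUE),
                     class = "texture_matrix"))
  }
  enc <- (a[sel] - 1L) * nb + b[sel]
  cnt <- tabulate(enc, nbins = nb * nb)
  C <- matrix(cnt, nb, nb)          # C[b, a] = ordered count (a then b)
  S <- C + t(C)
  structure(list(kind = "GLCM", matrix = S / sum(S),
                 offset = as.integer(offset), n_bins = nb,
                 n_pairs = sum(S), empty = FALSE),
            class = "texture_matrix")
}

# names of the 25 GLCM features, frozen order
glcm_feature_names <- function() c(
  "joint_maximum", "joint_average", "joint_variance", "joint_entropy",
  "difference_average", "difference_variance", "difference_entropy",
  "sum_average", "sum_variance", "sum_entropy", "angular_second_moment",
  "contrast", "dissimilarity", "inverse_difference",
  "inverse_difference_normalized", "inverse_difference_moment",
  "inverse_difference_moment_normalized", "inverse_variance", "correlation",
  "autocorrelation", "cluster_tendency", "cluster_shade",
  "cluster_prominence", "information_correlation_1",
  "information_correlation_2")

# the 25 features of one normalized symmetric GLCM
glcm_features_from_p <- function(P) {
  nb <- nrow(P)
  i <- row(P); j <- col(P)
  pi_marg <- rowSums(P)
  mu <- sum(i * P)                       # joint average (symmetric P)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

  # difference and sum distributions
  dk <- 0:(nb - 1)
  pdiff <- vapply(dk, function(k) sum(P[abs(i - j) == k]), numeric(1))
  sk <- 2:(2 * nb)
  psum <- vapply(sk, function(k) sum(P[(i + j) == k]), numeric(1))
  da <- sum(dk * pdiff)
  sa <- sum(sk * psum)

  sig2 <- sum((i - mu)^2 * P)            # marginal variance (symmetric)
  corr <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 0

  hxy <- ent(P)
  hx <- ent(pi_marg)
  pp <- outer(pi_marg, pi_marg)
  sel <- P > 0 & pp > 0
  hxy1 <- -sum(P[sel] * log2(pp[sel]))
  hxy2 <- ent(pp)
  ic1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  ic2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0

  c(joint_maximum = max(P),
    joint_average = mu,
    joint_variance = sum((i - mu)^2 * P),
    joint_entropy = hxy,
    difference_average = da,
    difference_variance = sum((dk - da)^2 * pdiff),
    difference_entropy = ent(pdiff),
    sum_average = sa,
    sum_variance = sum((sk - sa)^2 * psum),
    sum_entropy = ent(psum),
    angular_second_moment = sum(P^2),
    contrast = sum((i - j)^2 * P),
    dissimilarity = sum(abs(i - j) * P),
    inverse_difference = sum(P / (1 + abs(i - j))),
    inverse_difference_normalized = sum(P / (1 + abs(i - j) / nb)),
    inverse_difference_moment = sum(P / (1 + (i - j)^2)),
    inverse_difference_moment_normalized = sum(P / (1 + (i - j)^2 / nb^2)),
    inverse_variance = sum((P / (i - j)^2)[i != j]),
    correlation = corr,
    autocorrelation = sum(i * j * P),
    cluster_tendency = sum((i + j - 2 * mu)^2 * P),
    cluster_shade = sum((i + j - 2 * mu)^3 * P),
    cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    information_correlation_1 = ic1,
    information_correlation_2 = ic2)
}

#' GLCM texture features of a discretized ROI
#'
#' Computes the 25 co-occurrence features for each of the 13 directions at
#' the given distance and averages them arithmetically, making the result
#' rotationally invariant on isotropic grids. Directions with no valid voxel
#' pair are excluded from the average. With `aggregate = "merge"` the
#' normalized matrices are averaged first and the features computed once
#' (IBSI merged-matrix aggregation).
#'
#' @param roi a `discretized_roi`.
#' @param distance co-occurrence distance in voxel units.
#' @param aggregate `"average"` (per-direction features averaged) or
#'   `"merge"` (matrices merged, then features).
#' @return Named numeric vector of 25 features.
#' @export
glcm_features <- function(roi, distance = 1L,
                          aggregate = c("average", "merge")) {
  aggregate <- match.arg(aggregate)
  offs <- direction_offsets_3d()
  mats <- lapply(seq_len(nrow(offs)),
                 function(k) glcm_matrix(roi, offs[k, ], distance))
  valid <- !vapply(mats, `[[`, logical(1), "empty")
  if (!any(valid)) stop("no valid co-occurrence pairs in any direction")
  if (aggregate == "merge") {
    M <- Reduce(`+`, lapply(mats[valid], `[[`, "matrix")) / sum(valid)
    return(glcm_features_from_p(M))
  }
  F <- vapply(mats[valid],
              function(m) glcm_features_from_p(m$matrix),
              numeric(25L))
  rowMeans(F)
}

# maximal in-mask runs along one direction; a masked-out voxel breaks a run.
# returns list(lev, len) over all lines of the grid parallel to `d`.
runs_along <- function(lev, d) {
  dm <- dim(lev)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  n <- nx * ny * nz
  x <- rep_len(seq_len(nx), n)
  y <- rep(rep(seq_len(ny), each = nx), times = nz)
  z <- rep(seq_len(nz), each = nx * ny)
  back_steps <- function(c1, n1, d1) {
    if (d1 == 1L) c1 - 1L else if (d1 == -1L) n1 - c1 else rep(n, length(c1))
  }
  k <- pmin(back_steps(x, nx, d[1]), back_steps(y, ny, d[2]),
            back_steps(z, nz, d[3]))
  sx <- x - k * d[1]; sy <- y - k * d[2]; sz <- z - k * d[3]
  lid <- sx + (sy - 1L) * nx + (sz - 1L) * nx * ny
  ord <- order(lid, k)
  v <- as.vector(lev)[ord]
  l <- lid[ord]
  newrun <- c(TRUE, l[-1] != l[-n] | v[-1] != v[-n])
  runid <- cumsum(newrun)
  runlev <- v[newrun]
  runlen <- tabulate(runid)
  keep <- runlev > 0L
  list(lev = runlev[keep], len = runlen[keep])
}

#' Grey-level run-length matrix for one direction
#'
#' Counts maximal in-mask runs of identical grey level along the given
#' offset; a masked-out voxel terminates a run.
#'
#' @param roi a `discretized_roi`.
#' @param offset integer length-3 direction.
#' @return List of class `texture_matrix`: `kind = "GLRLM"`, `matrix` of run
#'   counts (`n_bins` rows, max run length columns), `n_runs`, `n_voxels`
#'   (in-mask voxels), `empty` flag.
#' @export
glrlm_matrix <- function(roi, offset) {
  stopifnot(inherits(roi, "discretized_roi"), length(offset) == 3)
  r <- runs_along(roi$levels, as.integer(offset))
  nb <- roi$n_bins
  nv <- sum(roi$levels > 0L)
  if (length(r$lev) == 0L) {
    return(structure(list(kind = "GLRLM", matrix = matrix(0, nb, 1L),
                          offset = as.integer(offset), n_bins = nb,
                          n_runs = 0L, n_voxels = nv, empty = TRUE),
                     class = "texture_matrix"))
  }
  lmax <- max(r$len)
  enc <- (r$len - 1L) * nb + r$lev
  cnt <- tabulate(enc, nbins = nb * lmax)
  M <- matrix(cnt, nb, lmax)
  structure(list(kind = "GLRLM", matrix = M, offset = as.integer(offset),
                 n_bins = nb, n_runs = sum(M), n_voxels = nv, empty = FALSE),
            class = "texture_matrix")
}

glrlm_feature_names <- function() c(
  "short_run_emphasis", "long_run_emphasis", "low_grey_level_run_emphasis",
  "high_grey_level_run_emphasis", "short_run_low_grey_level_emphasis",
  "short_run_high_grey_level_emphasis", "long_run_low_grey_level_emphasis",
  "long_run_high_grey_level_emphasis", "grey_level_non_uniformity",
  "grey_level_non_uniformity_normalized", "run_length_non_uniformity",
  "run_length_non_uniformity_normalized", "run_percentage",
  "grey_level_variance", "run_length_variance", "run_entropy")

# the 16 features of one run-length count matrix; nv = in-mask voxel count
glrlm_features_from_m <- function(M, nv) {
  ns <- sum(M)
  if (ns == 0) stop("empty run-length matrix")
  i <- row(M); j <- col(M)
  gi <- rowSums(M)
  rj <- colSums(M)
  ii <- seq_len(nrow(M)); jj <- seq_len(ncol(M))
  p <- M / ns
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  pe <- p[p > 0]
  c(short_run_emphasis = sum(rj / jj^2) / ns,
    long_run_emphasis = sum(rj * jj^2) / ns,
    low_grey_level_run_emphasis = sum(gi / ii^2) / ns,
    high_grey_level_run_emphasis = sum(gi * ii^2) / ns,
    short_run_low_grey_level_emphasis = sum(M / (i^2 * j^2)) / ns,
    short_run_high_grey_level_emphasis = sum(M * i^2 / j^2) / ns,
    long_run_low_grey_level_emphasis = sum(M * j^2 / i^2) / ns,
    long_run_high_grey_level_emphasis = sum(M * i^2 * j^2) / ns,
    grey_level_non_uniformity = sum(gi^2) / ns,
    grey_level_non_uniformity_normalized = sum(gi^2) / ns^2,
    run_length_non_uniformity = sum(rj^2) / ns,
    run_length_non_uniformity_normalized = sum(rj^2) / ns^2,
    run_percentage = ns / nv,
    grey_level_variance = sum((i - mu_i)^2 * p),
    run_length_variance = sum((j - mu_j)^2 * p),
    run_entropy = -sum(pe * log2(pe)))
}

#' GLRLM texture features of a discretized ROI
#'
#' The 16 run-length features per direction, averaged arithmetically over the
#' 13 directions (or computed once on the direction-merged count matrix with
#' `aggregate = "merge"`, in which case run percentage is normalized by
#' voxels x directions).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(roi, aggregate = c("average", "merge")) {
  aggregate <- match.arg(aggregate)
  offs <- direction_offsets_3d()
  mats <- lapply(seq_len(nrow(offs)), function(k) glrlm_matrix(roi, offs[k, ]))
  valid <- !vapply(mats, `[[`, logical(1), "empty")
  if (!any(valid)) stop("no runs in any direction")
  if (aggregate == "merge") {
    lmax <- max(vapply(mats[valid], function(m) ncol(m$matrix), integer(1)))
    M <- matrix(0, roi$n_bins, lmax)
    for (m in mats[valid]) M[, seq_len(ncol(m$matrix))] <-
        M[, seq_len(ncol(m$matrix))] + m$matrix
    return(glrlm_features_from_m(M, mats[[which(valid)[1]]]$n_voxels *
                                   sum(valid)))
  }
  F <- vapply(mats[valid],
              function(m) glrlm_features_from_m(m$matrix, m$n_voxels),
              numeric(16L))
  rowMeans(F)
}
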