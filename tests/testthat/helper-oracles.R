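# Independent brute-force oracles for texture features and ROC cutoffs.
# Everything here is written with explicit loops, separately from the
# package's vectorized implementations.

# symmetrized, normalized co-occurrence matrix by triple loop
oracle_glcm_matrix <- function(lev, n_bins, offset, distance = 1L) {
  d <- dim(lev)
  C <- matrix(0, n_bins, n_bins)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- lev[x, y, z]
    if (a == 0) next
    p <- c(x, y, z) + offset * distance
    if (any(p < 1) || any(p > d)) next
    b <- lev[p[1], p[2], p[3]]
    if (b == 0) next
    C[a, b] <- C[a, b] + 1
    C[b, a] <- C[b, a] + 1
  }
  if (sum(C) == 0) return(NULL)
  C / sum(C)
}

# the 25 co-occurrence features from a normalized matrix, by double loops
oracle_glcm_features <- function(P) {
  nb <- nrow(P)
  f <- numeric(0)
  mu <- 0
  for (i in 1:nb) for (j in 1:nb) mu <- mu + i * P[i, j]
  pi_m <- numeric(nb)
  for (i in 1:nb) for (j in 1:nb) pi_m[i] <- pi_m[i] + P[i, j]
  jvar <- jent <- asm <- contrast <- dissim <- invdiff <- invdiffn <- 0
  idm <- idmn <- invvar <- autoc <- ct <- cs <- cp <- 0
  for (i in 1:nb) for (j in 1:nb) {
    p <- P[i, j]
    jvar <- jvar + (i - mu)^2 * p
    if (p > 0) jent <- jent - p * log2(p)
    asm <- asm + p^2
    contrast <- contrast + (i - j)^2 * p
    dissim <- dissim + abs(i - j) * p
    invdiff <- invdiff + p / (1 + abs(i - j))
    invdiffn <- invdiffn + p / (1 + abs(i - j) / nb)
    idm <- idm + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + (i - j)^2 / nb^2)
    if (i != j) invvar <- invvar + p / (i - j)^2
    autoc <- autoc + i * j * p
    ct <- ct + (i + j - 2 * mu)^2 * p
    cs <- cs + (i + j - 2 * mu)^3 * p
    cp <- cp + (i + j - 2 * mu)^4 * p
  }
  pd <- numeric(nb)          # |i-j| = 0..nb-1
  ps <- numeric(2 * nb - 1)  # i+j = 2..2nb
  for (i in 1:nb) for (j in 1:nb) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + P[i, j]
  }
  da <- 0; for (k in 0:(nb - 1)) da <- da + k * pd[k + 1]
  dvar <- dent <- 0
  for (k in 0:(nb - 1)) {
    dvar <- dvar + (k - da)^2 * pd[k + 1]
    if (pd[k + 1] > 0) dent <- dent - pd[k + 1] * log2(pd[k + 1])
  }
  sa <- 0; for (k in 2:(2 * nb)) sa <- sa + k * ps[k - 1]
  svar <- sent <- 0
  for (k in 2:(2 * nb)) {
    svar <- svar + (k - sa)^2 * ps[k - 1]
    if (ps[k - 1] > 0) sent <- sent - ps[k - 1] * log2(ps[k - 1])
  }
  sig2 <- 0
  for (i in 1:nb) sig2 <- sig2 + (i - mu)^2 * pi_m[i]
  num <- 0
  for (i in 1:nb) for (j in 1:nb) num <- num + i * j * P[i, j]
  corr <- if (sig2 > 0) (num - mu^2) / sig2 else 0
  hx <- 0
  for (i in 1:nb) if (pi_m[i] > 0) hx <- hx - pi_m[i] * log2(pi_m[i])
  hxy1 <- hxy2 <- 0
  for (i in 1:nb) for (j in 1:nb) {
    pp <- pi_m[i] * pi_m[j]
    if (P[i, j] > 0 && pp > 0) hxy1 <- hxy1 - P[i, j] * log2(pp)
    if (pp > 0) hxy2 <- hxy2 - pp * log2(pp)
  }
  ic1 <- if (hx > 0) (jent - hxy1) / hx else 0
  ic2 <- if (hxy2 >= jent) sqrt(1 - exp(-2 * (hxy2 - jent))) else 0
  c(joint_maximum = max(P), joint_average = mu, joint_variance = jvar,
    joint_entropy = jent, difference_average = da,
    difference_variance = dvar, difference_entropy = dent,
    sum_average = sa, sum_variance = svar, sum_entropy = sent,
    angular_second_moment = asm, contrast = contrast,
    dissimilarity = dissim, inverse_difference = invdiff,
    inverse_difference_normalized = invdiffn,
    inverse_difference_moment = idm,
    inverse_difference_moment_normalized = idmn,
    inverse_variance = invvar, correlation = corr, autocorrelation = autoc,
    cluster_tendency = ct, cluster_shade = cs, cluster_prominence = cp,
    information_correlation_1 = ic1, information_correlation_2 = ic2)
}

# run-length counts by walking every line voxel-by-voxel
oracle_glrlm_matrix <- function(lev, n_bins, offset) {
  d <- dim(lev)
  runs_lev <- integer(0); runs_len <- integer(0)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    prev <- c(x, y, z) - offset
    if (all(prev >= 1) && all(prev <= d)) next     # not a line start
    p <- c(x, y, z)
    cur_lev <- -1L; cur_len <- 0L
    while (all(p >= 1) && all(p <= d)) {
      v <- lev[p[1], p[2], p[3]]
      if (v == cur_lev) {
        cur_len <- cur_len + 1L
      } else {
        if (cur_lev > 0L) {
          runs_lev <- c(runs_lev, cur_lev); runs_len <- c(runs_len, cur_len)
        }
        cur_lev <- v; cur_len <- 1L
      }
      p <- p + offset
    }
    if (cur_lev > 0L) {
      runs_lev <- c(runs_lev, cur_lev); runs_len <- c(runs_len, cur_len)
    }
  }
  if (length(runs_lev) == 0L) return(NULL)
  M <- matrix(0, n_bins, max(runs_len))
  for (r in seq_along(runs_lev))
    M[runs_lev[r], runs_len[r]] <- M[runs_lev[r], runs_len[r]] + 1
  M
}

oracle_glrlm_features <- function(M, nv) {
  ns <- sum(M)
  ng <- nrow(M); nl <- ncol(M)
  sre <- lre <- lglre <- hglre <- srlgle <- srhgle <- lrlgle <- lrhgle <- 0
  for (i in 1:ng) for (j in 1:nl) {
    m <- M[i, j]
    sre <- sre + m / j^2; lre <- lre + m * j^2
    lglre <- lglre + m / i^2; hglre <- hglre + m * i^2
    srlgle <- srlgle + m / (i^2 * j^2); srhgle <- srhgle + m * i^2 / j^2
    lrlgle <- lrlgle + m * j^2 / i^2; lrhgle <- lrhgle + m * i^2 * j^2
  }
  gln <- 0; for (i in 1:ng) gln <- gln + sum(M[i, ])^2
  rln <- 0; for (j in 1:nl) rln <- rln + sum(M[, j])^2
  mu_i <- mu_j <- 0
  for (i in 1:ng) for (j in 1:nl) {
    mu_i <- mu_i + i * M[i, j] / ns; mu_j <- mu_j + j * M[i, j] / ns
  }
  glv <- rlv <- rent <- 0
  for (i in 1:ng) for (j in 1:nl) {
    p <- M[i, j] / ns
    glv <- glv + (i - mu_i)^2 * p
    rlv <- rlv + (j - mu_j)^2 * p
    if (p > 0) rent <- rent - p * log2(p)
  }
  c(short_run_emphasis = sre / ns, long_run_emphasis = lre / ns,
    low_grey_level_run_emphasis = lglre / ns,
    high_grey_level_run_emphasis = hglre / ns,
    short_run_low_grey_level_emphasis = srlgle / ns,
    short_run_high_grey_level_emphasis = srhgle / ns,
    long_run_low_grey_level_emphasis = lrlgle / ns,
    long_run_high_grey_level_emphasis = lrhgle / ns,
    grey_level_non_uniformity = gln / ns,
    grey_level_non_uniformity_normalized = gln / ns^2,
    run_length_non_uniformity = rln / ns,
    run_length_non_uniformity_normalized = rln / ns^2,
    run_percentage = ns / nv, grey_level_variance = glv,
    run_length_variance = rlv, run_entropy = rent)
}

# 13-direction-averaged oracle features for a discretized ROI
oracle_texture_features <- function(lev, n_bins) {
  offs <- direction_offsets_3d()
  nv <- sum(lev > 0)
  gl <- list(); rl <- list()
  for (k in seq_len(nrow(offs))) {
    P <- oracle_glcm_matrix(lev, n_bins, offs[k, ])
    if (!is.null(P)) gl[[length(gl) + 1L]] <- oracle_glcm_features(P)
    M <- oracle_glrlm_matrix(lev, n_bins, offs[k, ])
    if (!is.null(M)) rl[[length(rl) + 1L]] <- oracle_glrlm_features(M, nv)
  }
  list(glcm = Reduce(`+`, gl) / length(gl),
       glrlm = Reduce(`+`, rl) / length(rl))
}

# random small discretized ROI (levels array with 0 = outside mask)
random_small_roi <- function(max_side = 6L, n_levels = 4L) {
  d <- sample(2:max_side, 3, replace = TRUE)
  lev <- array(sample(0:n_levels, prod(d), replace = TRUE,
                      prob = c(0.3, rep(0.7 / n_levels, n_levels))), dim = d)
  if (all(lev == 0)) lev[1] <- 1L
  structure(list(levels = lev, n_bins = as.integer(n_levels),
                 mask = mask3d(array(as.integer(lev > 0), dim = d)),
                 spacing = c(1, 1, 1)), class = "discretized_roi")
}

# exhaustive threshold search over every distinct confusion configuration
oracle_best_J <- function(scores, labels) {
  cand <- c(sort(unique(scores)) - 1e-9, max(scores) + 1e-9,
            sort(unique(scores)) + 1e-9)
  best <- -Inf
  for (c0 in cand) {
    tp <- sum(scores > c0 & labels == 1); fn <- sum(scores <= c0 & labels == 1)
    tn <- sum(scores <= c0 & labels == 0); fp <- sum(scores > c0 & labels == 0)
    J <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (J > best) best <- J
  }
  best
}

oracle_best_npv <- function(scores, labels) {
  cand <- c(sort(unique(scores)) - 1e-9, max(scores) + 1e-9,
            sort(unique(scores)) + 1e-9)
  best <- -Inf
  for (c0 in cand) {
    tn <- sum(scores <= c0 & labels == 0); fn <- sum(scores <= c0 & labels == 1)
    if (tn + fn == 0) next
    npv <- tn / (tn + fn)
    if (npv > best) best <- npv
  }
  best
}

# a tiny geometrically consistent bundle filled with given constants
toy_bundle <- function(dimv = c(6L, 6L, 4L), spacing = c(1, 1, 1),
                       t2w = 100, adc = 1000, uptake = 150, prob = 0.9) {
  mk <- function(v) volume3d(array(v, dim = dimv), spacing)
  case_bundle(t2w = mk(t2w), adc = mk(adc), uptake = mk(uptake),
              prob = mk(prob))
}

# compact phantom for fast geometric tests: small grid, small lesions
small_phantom_spec <- function(seed, grid = c(24L, 24L, 10L)) {
  phantom_spec(grid_shape = grid,
               low = list(vol_ml = c(0.04, 0.07), adc_mean = 1100,
                          adc_between_sd = 60, t2w_mean = 320,
                          corr_len_mm = 2.5),
               high = list(vol_ml = c(0.06, 0.09), adc_mean = 850,
                           adc_between_sd = 60, t2w_mean = 260,
                           corr_len_mm = 1.2),
               seed = seed)
}

# one cached small phantom cohort shared by the slower integration tests
shared_cohort <- local({
  cache <- NULL
  function(n = 10L, seed = 11L) {
    if (is.null(cache)) cache <<- simulate_cohort(n, seed = seed)
    cache
  }
})
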