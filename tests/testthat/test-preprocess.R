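test_that("Gaussian de-noising matches the sampled separable kernel", {
  # unit impulse: output is the normalized 3D Gaussian kernel
  a <- array(0, dim = c(9, 9, 9)); a[5, 5, 5] <- 1
  v <- denoise_gaussian(volume3d(a, c(1, 1, 1)), sigma_mm = 0.5)
  r <- 2L                                      # ceiling(4 * 0.5)
  k1 <- exp(-((-r):r)^2 / (2 * 0.5^2)); k1 <- k1 / sum(k1)
  expected <- array(0, dim = c(9, 9, 9))
  for (i in -r:r) for (j in -r:r) for (l in -r:r)
    expected[5 + i, 5 + j, 5 + l] <- k1[i + r + 1] * k1[j + r + 1] *
      k1[l + r + 1]
  expect_equal(v$data, expected, tolerance = 1e-12)

  # anisotropic spacing: physical sigma converts per axis; the impulse
  # response is the product of the three per-axis sampled kernels
  a2 <- array(0, dim = c(17, 9, 9)); a2[9, 5, 5] <- 1
  v2 <- denoise_gaussian(volume3d(a2, c(0.5, 1, 2)), sigma_mm = 0.5)
  expect_equal(sum(v2$data), 1, tolerance = 1e-12)
  kfor <- function(sig_vox) {
    r <- max(1L, ceiling(4 * sig_vox))
    k <- exp(-((-r):r)^2 / (2 * sig_vox^2)); k / sum(k)
  }
  kx <- kfor(1); ky <- kfor(0.5); kz <- kfor(0.25)
  exp2 <- array(0, dim = c(17, 9, 9))
  for (i in seq_along(kx)) for (j in seq_along(ky)) for (l in seq_along(kz))
    exp2[9 + i - 5, 5 + j - 3, 5 + l - 2] <- kx[i] * ky[j] * kz[l]
  expect_equal(v2$data, exp2, tolerance = 1e-12)
})

test_that("de-noising preserves constants and sigma 0 is the identity", {
  v <- volume3d(array(7, dim = c(6, 5, 4)), c(0.6, 0.6, 1.2))
  expect_equal(denoise_gaussian(v, 1.0)$data,
               v$data + 0 * v$data, tolerance = 1e-12)
  expect_identical(denoise_gaussian(v, 0), v)
})

test_that("isotropic resampling is exact on identity and affine inputs", {
  a <- array(rnorm(4 * 5 * 6), dim = c(4, 5, 6))
  v <- volume3d(a, c(0.5, 0.5, 0.5))
  expect_equal(resample_isotropic(v, 0.5)$data, a, tolerance = 1e-14)

  # linear ramp along x at 1 mm, to 0.5 mm: trilinear reproduces the ramp
  n <- 8L
  ramp <- array(rep((0:(n - 1)) * 1.0, 5 * 3), dim = c(n, 5, 3))
  rv <- resample_isotropic(volume3d(ramp, c(1, 1, 1)), 0.5)
  m <- dim(rv$data)[1]
  expected_x <- pmin((0:(m - 1)) * 0.5, n - 1)   # clamped at the far edge
  expect_equal(rv$data[, 1, 1], expected_x, tolerance = 1e-12)
  expect_equal(rv$spacing, c(0.5, 0.5, 0.5))
})

test_that("nearest-neighbour mask resampling stays binary, volume stable", {
  set.seed(31)
  d <- c(20L, 20L, 8L)
  blob <- array(0L, dim = d)
  ctr <- (d + 1) / 2
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3])
    if (sum(((c(x, y, z) - ctr) / c(6, 7, 3))^2) <= 1) blob[x, y, z] <- 1L
  m <- mask3d(blob, spacing = c(0.8, 0.8, 2.4))
  rm <- resample_isotropic(m, 0.5)
  expect_true(all(rm$data %in% c(0L, 1L)))
  v_in <- mask_count(m) * prod(m$spacing)
  v_out <- mask_count(rm) * prod(rm$spacing)
  expect_lt(abs(v_out - v_in) / v_in, 0.15)
  expect_lt(abs(roi_volume(rm) - roi_volume(m)) / roi_volume(m), 0.15)
})

test_that("re-segmentation follows the interpolated-percentile convention", {
  d <- c(10L, 10L, 1L)
  v <- volume3d(array(as.numeric(1:100), dim = d), c(1, 1, 1))
  m <- mask3d(array(1L, dim = d))
  # P1 = 1.99 and P99 = 99.01 under linear interpolation: values 1 and 100 go
  r <- resegment_roi(v, m, 1, 99)
  expect_equal(mask_count(r), 98L)
  expect_equal(sort(v$data[r$data == 1L]), as.numeric(2:99))

  expect_equal(resegment_roi(v, m, 0, 100)$data, m$data)    # full range
  vc <- volume3d(array(5, dim = d), c(1, 1, 1))
  expect_equal(resegment_roi(vc, m, 1, 99)$data, m$data)    # constant ROI

  # idempotent: re-applying on its own output changes nothing
  r2 <- resegment_roi(v, r, 0, 100)
  expect_equal(r2$data, r$data)

  # a band containing no observed value empties the mask
  v2 <- volume3d(array(c(1, 100), dim = c(2, 1, 1)), c(1, 1, 1))
  m2 <- mask3d(array(1L, dim = c(2, 1, 1)))
  expect_error(resegment_roi(v2, m2, 40, 60), "removed all voxels")
})

test_that("FBN discretization maps min/max to 1/n_bins and is affine-invariant", {
  d <- c(4L, 1L, 1L)
  v <- volume3d(array(c(0, 1, 2, 3), dim = d), c(1, 1, 1))
  m <- mask3d(array(1L, dim = d))
  expect_equal(as.vector(discretize_fbn(v, m, 4)$levels), c(1L, 2L, 3L, 4L))

  vc <- volume3d(array(9, dim = d), c(1, 1, 1))
  expect_true(all(discretize_fbn(vc, m, 16)$levels[m$data == 1] == 1L))

  set.seed(7)
  for (rep in 1:5) {
    x <- array(rnorm(60), dim = c(5, 4, 3))
    msk <- mask3d(array(rbinom(60, 1, 0.8), dim = c(5, 4, 3)))
    if (mask_count(msk) == 0) next
    l1 <- discretize_fbn(volume3d(x, c(1, 1, 1)), msk, 8)$levels
    l2 <- discretize_fbn(volume3d(3.7 * x + 11, c(1, 1, 1)), msk, 8)$levels
    expect_identical(l1, l2)
    inm <- msk$data == 1L
    expect_equal(l1[inm][which.max(x[inm])], 8L)
    expect_equal(l1[inm][which.min(x[inm])], 1L)
    expect_true(all(l1[inm] >= 1L & l1[inm] <= 8L))
  }
})
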