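test_that("voxel filtering equals the three-rule conjunction (truth table)", {
  cfg <- detection_config()
  # 8 voxels, one per pass/fail combination of the three rules
  pass_prob <- c(0.7, 0.3)          # >= 0.60 vs below
  pass_adc <- c(800, 1700)          # in [200, 1600] vs above
  pass_uptake <- c(150, 50)         # >= 100 vs below
  combos <- expand.grid(p = 1:2, a = 1:2, u = 1:2)
  d <- c(2L, 2L, 2L)
  prob <- array(pass_prob[combos$p], dim = d)
  adc <- array(pass_adc[combos$a], dim = d)
  uptake <- array(pass_uptake[combos$u], dim = d)
  b <- case_bundle(t2w = volume3d(array(100, d), c(1, 1, 1)),
                   adc = volume3d(adc, c(1, 1, 1)),
                   uptake = volume3d(uptake, c(1, 1, 1)),
                   prob = volume3d(prob, c(1, 1, 1)))
  kept <- filter_voxels(b, cfg)
  expected <- as.integer(combos$p == 1 & combos$a == 1 & combos$u == 1)
  expect_identical(as.vector(kept$data), expected)

  # boundary semantics: keep-inclusive thresholds
  bb <- toy_bundle(c(1L, 1L, 1L), adc = 1600, prob = 0.60, uptake = 100)
  expect_equal(mask_count(filter_voxels(bb, cfg)), 1L)
  bb2 <- toy_bundle(c(1L, 1L, 1L), adc = 200, prob = 0.60, uptake = 100)
  expect_equal(mask_count(filter_voxels(bb2, cfg)), 1L)
  bb3 <- toy_bundle(c(1L, 1L, 1L), adc = 1700, prob = 0.7, uptake = 150)
  expect_equal(mask_count(filter_voxels(bb3, cfg)), 0L)
})

test_that("filtering is monotone in every threshold", {
  set.seed(12)
  d <- c(8L, 8L, 4L)
  b <- case_bundle(t2w = volume3d(array(100, d), c(1, 1, 1)),
                   adc = volume3d(array(runif(prod(d), 0, 2000), d), c(1, 1, 1)),
                   uptake = volume3d(array(runif(prod(d), 0, 200), d), c(1, 1, 1)),
                   prob = volume3d(array(runif(prod(d)), d), c(1, 1, 1)))
  strict <- filter_voxels(b, detection_config())
  relaxed <- filter_voxels(b, detection_config(prob_min = 0.4, adc_min = 100,
                                               adc_max = 1800,
                                               uptake_min = 50))
  expect_true(all(relaxed$data >= strict$data))
})

test_that("candidate area thresholding keeps 125 mm^2, drops 75 mm^2 blobs", {
  d <- c(40L, 40L, 3L)
  sp <- c(0.5, 0.5, 0.5)
  big <- array(0L, dim = d); big[1:25, 1:20, 2] <- 1L     # 500 vox = 125 mm^2
  small <- array(0L, dim = d); small[1:20, 1:15, 2] <- 1L # 300 vox = 75 mm^2
  cfg <- detection_config()
  cb <- extract_candidates(mask3d(big, sp), cfg)
  expect_equal(length(cb), 1L)
  expect_equal(cb[[1]]$max_axial_area_mm2, 125)
  cs <- extract_candidates(mask3d(small, sp), cfg)
  expect_equal(length(cs), 0L)

  # two disjoint qualifying blobs: larger volume first
  two <- array(0L, dim = d)
  two[1:25, 1:20, 2] <- 1L              # 500 voxels, area 125 mm^2
  two[1:24, 23:40, 1:3] <- 1L           # 432/slice = 108 mm^2, 1296 voxels
  ct <- extract_candidates(mask3d(two, sp), cfg)
  expect_equal(length(ct), 2L)
  expect_gt(ct[[1]]$volume_mm3, ct[[2]]$volume_mm3)

  # empty kept mask is an empty candidate list, not an error
  expect_equal(length(extract_candidates(mask3d(array(0L, d), sp), cfg)), 0L)

  # candidate count is non-increasing in the area threshold
  n_strict <- length(extract_candidates(mask3d(two, sp),
                                        detection_config(min_area_mm2 = 130)))
  expect_lte(n_strict, length(ct))
})

test_that("26-connectivity joins diagonal voxels, 6-connectivity splits them", {
  d <- c(30L, 30L, 2L)
  diag2 <- array(0L, dim = d)
  diag2[1:15, 1:15, 1] <- 1L
  diag2[16:30, 16:30, 1] <- 1L          # touch only at a corner
  m <- mask3d(diag2, c(1, 1, 1))
  expect_equal(length(extract_candidates(m, detection_config(
    min_area_mm2 = 100, connectivity = 26L))), 1L)
  expect_equal(length(extract_candidates(m, detection_config(
    min_area_mm2 = 100, connectivity = 6L))), 2L)
})

test_that("lesion selection picks the maximal-Dice candidate", {
  d <- c(10L, 10L, 2L)
  ref <- array(0L, dim = d); ref[1:5, 1:5, 1] <- 1L
  refm <- mask3d(ref, c(1, 1, 1))
  mk_cand <- function(idx) structure(
    list(voxel_indices = idx, max_axial_area_mm2 = 999,
         volume_mm3 = length(idx), centroid = c(0, 0, 0), label = 1L),
    class = "candidate_region")
  ref_idx <- which(ref == 1L)
  cands <- list(mk_cand(ref_idx[1:5]),               # partial overlap
                mk_cand(setdiff(seq_len(prod(d)), ref_idx)[1:10]), # disjoint
                mk_cand(ref_idx))                    # exact match
  sel <- select_lesion(cands, refm)
  expect_equal(attr(sel, "dice"), 1)
  expect_identical(sel$voxel_indices, ref_idx)
  # brute-force Dice ordering
  dc <- vapply(cands, dice_overlap, numeric(1), b = refm)
  expect_equal(which.max(dc), 3L)
  expect_null(select_lesion(list(), refm))
})
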