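test_that("min-max normalization scales training columns to [0,1]", {
  tbl <- feature_table(cbind(a = c(2, 4, 6), b = c(1, 1, 2)), c(0, 1, 1))
  fit <- minmax_fit_apply(tbl)
  expect_equal(fit$table$x[, "a"], c(0, 0.5, 1), ignore_attr = TRUE)
  # held-out values extrapolate, unclipped
  held <- minmax_apply(cbind(a = 8, b = 1), fit$params)
  expect_equal(unname(held[1, "a"]), 1.5)
  # constant column maps to 0 with a warning
  tc <- feature_table(cbind(a = c(1, 2, 3), k = c(5, 5, 5)), c(0, 1, 1))
  expect_warning(fc <- minmax_fit_apply(tc), "constant")
  expect_true(all(fc$table$x[, "k"] == 0))
})

test_that("the AUC estimator handles separation and ties correctly", {
  expect_equal(auc_mw(c(2, 3, 0, 1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_mw(c(1, 1, 1, 1), c(1, 1, 0, 0)), 0.5)
  expect_equal(auc_mw(c(0.9, 0.1, 0.8, 0.2), c(1, 0, 1, 0)), 1.0)
  # one inversion among 2x2 pairs
  expect_equal(auc_mw(c(3, 1, 2, 0), c(1, 1, 0, 0)), 0.75)
})

test_that("bootstrap AUC: separation gives a degenerate CI, null stays near 0.5", {
  sep <- bootstrap_auc(c(rep(1, 10), rep(0, 10)), c(rep(1, 10), rep(0, 10)),
                       n_boot = 200, seed = 3)
  expect_equal(sep$auc, 1.0)
  expect_equal(c(sep$ci_lo, sep$ci_hi), c(1, 1))

  set.seed(8)
  x <- rnorm(400)
  lab <- rep(c(0, 1), each = 200)
  nul <- bootstrap_auc(x, lab, n_boot = 300, seed = 4)
  expect_gte(nul$auc, 0.5 - 1e-12)   # folded orientation
  expect_lte(nul$auc, 0.6)
  # anti-discriminative features fold to the same ranking value
  inf <- rnorm(400) + 1.5 * lab
  up <- bootstrap_auc(inf, lab, n_boot = 200, seed = 5)
  dn <- bootstrap_auc(-inf, lab, n_boot = 200, seed = 5)
  expect_equal(up$auc, dn$auc)
  expect_true(dn$folded)
})

test_that("correlation pruning drops the lower-AUC member above the threshold", {
  set.seed(41)
  x <- rnorm(100)
  tbl <- feature_table(cbind(a = x, b = x, c = rnorm(100)),
                       rep(c(0, 1), 50))
  res <- prune_correlated(tbl, c(a = 0.8, b = 0.6, c = 0.7), rho_max = 0.9)
  expect_identical(res$kept, c("a", "c"))
  expect_equal(res$removed$dropped, "b")
  expect_equal(res$removed$rho, 1)

  # a pair exactly at the threshold is kept ("strictly higher than")
  z <- rnorm(100)
  zs <- as.vector(scale(x)); rs <- as.vector(scale(resid(lm(z ~ x))))
  y <- 0.9 * zs + sqrt(1 - 0.81) * rs
  tbl2 <- feature_table(cbind(a = x, b = y), rep(c(0, 1), 50))
  rho_exact <- abs(cor(tbl2$x))["a", "b"]   # same code path as the pruner
  res2 <- prune_correlated(tbl2, c(a = 0.9, b = 0.5), rho_max = rho_exact)
  expect_identical(res2$kept, c("a", "b"))

  # three mutually correlated columns: only the best survives
  f <- rnorm(300)
  blk <- cbind(g1 = f + 0.1 * rnorm(300), g2 = f + 0.1 * rnorm(300),
               g3 = f + 0.1 * rnorm(300))
  stopifnot(min(abs(cor(blk)[upper.tri(diag(3))])) > 0.9)
  tbl3 <- feature_table(blk, rep(c(0, 1), 150))
  aucs3 <- c(g1 = 0.9, g2 = 0.8, g3 = 0.7)
  res3 <- prune_correlated(tbl3, aucs3, rho_max = 0.9)
  # exhaustive greedy oracle on 3 columns
  cm <- abs(cor(blk))
  alive <- c(TRUE, TRUE, TRUE)
  prs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  prs <- prs[order(cm[prs], decreasing = TRUE), ]
  for (r in 1:3) {
    i <- prs[r, 1]; j <- prs[r, 2]
    if (alive[i] && alive[j] && cm[i, j] > 0.9)
      alive[if (aucs3[i] < aucs3[j]) i else j] <- FALSE
  }
  expect_identical(res3$kept, names(aucs3)[alive])
  expect_identical(res3$kept, "g1")

  # surviving set has no examined pair above the threshold
  surv <- abs(cor(tbl3$x[, res3$kept, drop = FALSE]))
  expect_true(all(surv[upper.tri(surv)] <= 0.9))
})

test_that("wrapper selection degenerates correctly and is deterministic", {
  spec <- table_spec(n_rows = 80, n_features = 6, informative = 1:2,
                     delta_mu = 2, seed = 13)
  tbl <- minmax_fit_apply(simulate_feature_table(spec))$table
  ranked <- paste0("f", 1:6)
  one <- wrapper_select(tbl, ranked, max_n = 1, seed = 2)
  expect_equal(one$subset_size_n, 1L)
  expect_equal(length(one$test_acc_curve), 1L)

  a <- wrapper_select(tbl, ranked, max_n = 6, seed = 2)
  b <- wrapper_select(tbl, ranked, max_n = 6, seed = 2)
  expect_identical(a$subset, b$subset)
  expect_identical(a$test_acc_curve, b$test_acc_curve)
  expect_gte(a$subset_size_n, 1L)
  expect_equal(length(a$train_acc_curve), 6L)
})

test_that("grouped folds never split a patient and stay stratified", {
  labels <- rep(c(0, 0, 1, 1), 10)
  patient <- rep(1:20, each = 2)          # two lesions per patient
  fold <- pcarad:::make_folds(labels, patient, k = 4, seed = 9)
  expect_equal(length(unique(fold)), 4L)
  for (p in unique(patient))
    expect_equal(length(unique(fold[patient == p])), 1L)
  for (f in 1:4)
    expect_equal(length(unique(labels[fold != f])), 2L)
})

test_that("box-constraint search prefers the smallest C on ties", {
  spec <- table_spec(n_rows = 60, n_features = 3, informative = 1:2,
                     delta_mu = 6, seed = 5)     # effectively separable
  tbl <- minmax_fit_apply(simulate_feature_table(spec))$table
  g <- grid_search_C(tbl, c("f1", "f2"), C_grid = 1:10, seed = 3)
  expect_equal(g$best_C, 1L)
  expect_equal(length(g$accuracy_curve), 10L)
  g2 <- grid_search_C(tbl, c("f1", "f2"), C_grid = 1:10, seed = 3)
  expect_identical(g$accuracy_curve, g2$accuracy_curve)
})
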