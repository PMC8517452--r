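test_that("the trained scorer separates a separable table and is monotone", {
  spec <- table_spec(n_rows = 60, n_features = 4, informative = 1:2,
                     delta_mu = 6, seed = 17)
  raw <- simulate_feature_table(spec)
  fit <- minmax_fit_apply(raw)
  sc <- train_scorer(fit$table, c("f1", "f2"), C = 1,
                     normalization = fit$params)
  s <- score_lesions(sc, raw$x)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(mean((s > 0.5) == (raw$labels == 1)), 1.0)

  # score is monotone nondecreasing in the oriented decision value
  xn <- minmax_apply(raw$x, fit$params)[, sc$subset, drop = FALSE]
  dv <- sc$sign * pcarad:::kernel_decision(sc$sv, sc$coefs, sc$rho, sc$gamma,
                                           sc$coef0, sc$degree, xn)
  expect_true(all(diff(s[order(dv)]) >= 0))

  # recomputed decision values equal e1071's own
  m <- pcarad:::fit_poly_svm(fit$table$x[, c("f1", "f2")], fit$table$labels)
  dv_pkg <- pcarad:::kernel_decision(m$SV, m$coefs, m$rho, m$gamma, m$coef0,
                                     m$degree, fit$table$x[, c("f1", "f2")])
  dv_e1071 <- attr(predict(m, fit$table$x[, c("f1", "f2")],
                           decision.values = TRUE), "decision.values")
  expect_equal(unname(dv_pkg), unname(dv_e1071[, 1]), tolerance = 1e-8)

  # scoring twice is identical; missing features are named
  expect_identical(score_lesions(sc, raw$x), s)
  expect_error(score_lesions(sc, raw$x[, -1]), "f1")
  expect_error(train_scorer(feature_table(raw$x, rep(1, 60)), "f1"),
               "both classes")
})

test_that("held-out discrimination is high at 2-sigma class separation", {
  aucs <- vapply(1:10, function(s) {
    tr <- simulate_feature_table(table_spec(n_rows = 160, n_features = 5,
                                            informative = 1:3, delta_mu = 2,
                                            seed = 100 + s))
    te <- simulate_feature_table(table_spec(n_rows = 160, n_features = 5,
                                            informative = 1:3, delta_mu = 2,
                                            seed = 900 + s))
    fit <- minmax_fit_apply(tr)
    sc <- train_scorer(fit$table, paste0("f", 1:3), C = 1,
                       normalization = fit$params)
    auc_mw(score_lesions(sc, te$x), te$labels)
  }, numeric(1))
  expect_true(all(aucs >= 0.90))
  # class-centroid ordering
  tr <- simulate_feature_table(table_spec(seed = 1, n_features = 5,
                                          informative = 1:3, delta_mu = 2))
  fit <- minmax_fit_apply(tr)
  sc <- train_scorer(fit$table, paste0("f", 1:3), normalization = fit$params)
  cpos <- colMeans(tr$x[tr$labels == 1, ])
  cneg <- colMeans(tr$x[tr$labels == 0, ])
  expect_gt(score_lesions(sc, cpos), score_lesions(sc, cneg))
})

test_that("Youden cutoff equals exhaustive threshold search", {
  # perfect separation: the wide-gap midpoint
  y1 <- youden_cutoff(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(as.numeric(y1), 0.5)
  expect_equal(attr(y1, "J"), 1)

  # worked example: max J = 0.5, attained in (0.6, 0.9)
  y2 <- youden_cutoff(c(0.9, 0.4, 0.1, 0.6), c(1, 1, 0, 0))
  expect_equal(attr(y2, "J"), 0.5)
  expect_gt(as.numeric(y2), 0.6)
  expect_lt(as.numeric(y2), 0.9)

  # J is invariant under strictly monotone transforms
  set.seed(6)
  s <- runif(40); l <- rbinom(40, 1, 0.5); l[1:2] <- c(0, 1)
  expect_equal(attr(youden_cutoff(s, l), "J"),
               attr(youden_cutoff(qlogis(s / 2 + 0.25), l), "J"))

  # random instances against the brute-force oracle
  for (rep in 1:40) {
    n <- sample(6:30, 1)
    s <- round(runif(n), 2)              # force ties sometimes
    l <- rbinom(n, 1, 0.5); l[1:2] <- c(0, 1)
    yc <- youden_cutoff(s, l)
    expect_equal(attr(yc, "J"), oracle_best_J(s, l), tolerance = 1e-12)
  }
})

test_that("NPV-max cutoff achieves the oracle NPV with zero false negatives", {
  n1 <- npv_max_cutoff(c(0.8, 0.9, 0.1, 0.2, 0.85), c(1, 1, 0, 0, 0))
  expect_equal(attr(n1, "npv"), 1)
  # calls exactly {0.1, 0.2} negative
  expect_true(as.numeric(n1) >= 0.2 && as.numeric(n1) < 0.8)

  # perfectly separated: NPV 1 and sensitivity 1 at the cutoff
  n2 <- npv_max_cutoff(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0))
  cm <- confusion_metrics(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0),
                          as.numeric(n2))
  expect_equal(as.numeric(cm$npv), 1)
  expect_equal(as.numeric(cm$sensitivity), 1)
  expect_lte(as.numeric(n2), as.numeric(youden_cutoff(
    c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0))))

  # random instances: achieved NPV equals the exhaustive-search optimum
  for (rep in 1:40) {
    set.seed(300 + rep)
    n <- sample(8:40, 1)
    s <- sample(seq(0.01, 0.99, by = 0.01), n)   # distinct
    l <- rbinom(n, 1, 0.4); l[1:2] <- c(0, 1)
    nc <- npv_max_cutoff(s, l)
    expect_equal(attr(nc, "npv"), oracle_best_npv(s, l), tolerance = 1e-12)
  }

  # on trained (distinct, class-ordered) scores the cutoff misses no positive
  tr <- simulate_feature_table(table_spec(n_rows = 80, n_features = 5,
                                          informative = 1:3, delta_mu = 1.5,
                                          seed = 33))
  fit <- minmax_fit_apply(tr)
  sc <- train_scorer(fit$table, paste0("f", 1:3), normalization = fit$params)
  s_tr <- score_lesions(sc, tr$x)
  nc_tr <- npv_max_cutoff(s_tr, tr$labels)
  cc_tr <- pcarad:::confusion_counts(s_tr, tr$labels, as.numeric(nc_tr))
  expect_equal(cc_tr[["fn"]], 0L)
  expect_equal(attr(nc_tr, "npv"), 1)
})

test_that("aggressiveness banding partitions scores at the documented edges", {
  cuts <- cutoff_set(youden = 0.42, npv_max = 0.39)
  lv <- function(r) as.character(assign_agg_score(r, cuts)$level)
  expect_equal(lv(0.50), "aggressive")
  expect_equal(lv(0.30), "indolent")        # 0.30 <= 0.85 * 0.42 = 0.357
  expect_equal(lv(0.40), "indeterminate")   # 0.357 < 0.40 <= 0.42
  expect_equal(lv(0.42), "indeterminate")   # aggressive only strictly above
  expect_equal(lv(0.357), "indolent")       # boundary belongs to indolent

  # partition and monotonicity over a grid
  g <- seq(0, 1, by = 0.001)
  bands <- assign_agg_score(g, cuts)$level
  expect_false(anyNA(bands))
  expect_true(all(diff(as.integer(bands)) >= 0))
})

test_that("waterfall data is a shifted permutation consistent with the call", {
  s <- c(0.9, 0.1, 0.42, 0.6, 0.3)
  l <- c(1, 0, 0, 1, 0)
  wf <- waterfall_data(s, l, 0.42)
  expect_equal(sort(wf$normalized_score), sort(s - 0.42))
  expect_true(all(diff(wf$normalized_score) <= 0))
  cuts <- cutoff_set(0.42, 0.39)
  agg <- assign_agg_score(s, cuts)$level == "aggressive"
  expect_equal(wf$normalized_score > 0,
               agg[order(s, decreasing = TRUE)], ignore_attr = TRUE)
  wf0 <- waterfall_data(rep(0.4, 4), c(1, 0, 1, 0), 0.4)
  expect_true(all(wf0$normalized_score == 0))
})

test_that("agg_fit returns a coherent model object with working methods", {
  spec <- table_spec(n_rows = 100, n_features = 10, informative = 1:3,
                     delta_mu = 2, seed = 23,
                     corr_blocks = list(list(cols = 8:10, rho = 0.95)))
  tbl <- simulate_feature_table(spec)
  m <- agg_fit(tbl, n_boot = 150, C_grid = 1:5, seed = 2)
  expect_s3_class(m, "agg_model")
  expect_gte(m$fs$subset_size_n, 1L)
  expect_true(nrow(m$pruning$removed) >= 2)          # the rho=0.95 block
  expect_output(print(m), "polynomial-kernel")
  expect_silent(cf <- coef(m))
  expect_equal(cf$feature, m$fs$subset)
  p <- predict(m, tbl$x, type = "band")
  expect_equal(p$raw_score, m$train_scores, tolerance = 1e-12)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
})
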