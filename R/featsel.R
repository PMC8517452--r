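# run expr with a local RNG state seeded by `seed`, restoring the caller's
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Mann-Whitney AUC of a single feature
#'
#' Tie-corrected rank (Mann-Whitney) estimator of the area under the ROC
#' curve of `x` for predicting `labels == 1`.
#'
#' @param x numeric feature values.
#' @param labels binary labels (1 = positive class).
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(x, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(x)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Assemble a feature table
#'
#' @param features numeric matrix or data.frame, one row per lesion, named
#'   feature columns.
#' @param labels binary vector: 1 = aggressive (GG > 2), 0 = low-aggressive
#'   (GG <= 2).
#' @param patient_id optional patient identifier per row (defaults to one
#'   patient per lesion); used for grouped cross-validation folds.
#' @return A `feature_table`: list with `x` (numeric matrix), `labels`,
#'   `patient_id`.
#' @export
feature_table <- function(features, labels, patient_id = NULL) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  labels <- as.integer(labels)
  stopifnot(nrow(x) == length(labels), all(labels %in% 0:1),
            !anyNA(x), all(is.finite(x)))
  if (is.null(patient_id)) patient_id <- seq_len(nrow(x))
  stopifnot(length(patient_id) == nrow(x))
  structure(list(x = x, labels = labels, patient_id = patient_id),
            class = "feature_table")
}

#' Min-max normalization: fit on training rows, apply anywhere
#'
#' `minmax_fit` learns the per-feature (min, max) on the training table;
#' `minmax_apply` rescales a matrix to `(x - min) / (max - min)`. Training
#' rows land in `[0, 1]`; held-out rows may fall outside and are not clipped.
#' A constant feature maps to 0 (with a warning at fit time).
#'
#' @param table a [feature_table()].
#' @return `minmax_fit`: a `minmax_params` list with `min`, `max`;
#'   `minmax_apply`: the rescaled matrix.
#' @export
minmax_fit <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  mn <- apply(table$x, 2, min)
  mx <- apply(table$x, 2, max)
  if (any(mx <= mn))
    warning("constant feature(s) map to 0: ",
            paste(colnames(table$x)[mx <= mn], collapse = ", "))
  structure(list(min = mn, max = mx), class = "minmax_params")
}

#' @rdname minmax_fit
#' @param x numeric matrix with the same columns as the fitted table.
#' @param params a `minmax_params`.
#' @export
minmax_apply <- function(x, params) {
  x <- as.matrix(x)
  miss <- setdiff(names(params$min), colnames(x))
  if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
  x <- x[, names(params$min), drop = FALSE]
  rng <- params$max - params$min
  rng[rng <= 0] <- 1      # constant feature: numerator is 0 on training rows
  sweep(sweep(x, 2, params$min, "-"), 2, rng, "/")
}

#' @rdname minmax_fit
#' @param table a [feature_table()].
#' @export
minmax_fit_apply <- function(table) {
  p <- minmax_fit(table)
  out <- table
  out$x <- minmax_apply(table$x, p)
  list(table = out, params = p)
}

#' Bootstrap AUC of a single feature
#'
#' The feature's direction is first folded so that its full-sample AUC is
#' >= 0.5 (features where low values mark aggressiveness rank equally with
#' ones where high values do). The point estimate is the mean Mann-Whitney
#' AUC over case-resampled bootstrap replicates; the confidence interval is
#' the percentile 2.5/97.5 interval. Replicates missing a class are redrawn.
#'
#' @param x numeric feature values.
#' @param labels binary labels.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @return List with `auc`, `ci_lo`, `ci_hi`, `folded` (logical).
#' @export
bootstrap_auc <- function(x, labels, n_boot = 1000L, seed = 1L) {
  stopifnot(n_boot >= 100L)
  labels <- as.integer(labels)
  folded <- auc_mw(x, labels) < 0.5
  xx <- if (folded) -x else x
  n <- length(xx)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L) break
      }
      auc_mw(xx[idx], labels[idx])
    }, numeric(1))
  })
  list(auc = mean(reps),
       ci_lo = unname(stats::quantile(reps, 0.025, type = 7)),
       ci_hi = unname(stats::quantile(reps, 0.975, type = 7)),
       folded = folded)
}

#' Bootstrap AUC for every column of a feature table
#'
#' @param table a [feature_table()].
#' @param n_boot bootstrap replicates per feature.
#' @param seed integer seed (per-feature seeds are derived from it).
#' @return data.frame with `feature`, `auc`, `ci_lo`, `ci_hi`, `folded`,
#'   sorted in the table's column order.
#' @export
bootstrap_auc_table <- function(table, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  res <- lapply(seq_len(ncol(table$x)), function(j)
    bootstrap_auc(table$x[, j], table$labels, n_boot = n_boot,
                  seed = (seed + j) %% .Machine$integer.max))
  data.frame(feature = colnames(table$x),
             auc = vapply(res, `[[`, numeric(1), "auc"),
             ci_lo = vapply(res, `[[`, numeric(1), "ci_lo"),
             ci_hi = vapply(res, `[[`, numeric(1), "ci_hi"),
             folded = vapply(res, `[[`, logical(1), "folded"))
}

#' Drop the lower-AUC member of highly correlated feature pairs
#'
#' Feature pairs with `|Pearson rho| > rho_max` are visited in descending
#' `|rho|`; in each surviving pair the member with the lower AUC is dropped
#' (AUC ties broken by keeping the earlier feature in canonical column
#' order). A pair at exactly `rho_max` is kept. Deterministic.
#'
#' @param table a [feature_table()].
#' @param aucs named numeric vector of per-feature AUCs (e.g. the `auc`
#'   column of [bootstrap_auc_table()] named by `feature`).
#' @param rho_max correlation threshold (default 0.9).
#' @return List with `kept` (feature names, original order) and `removed`
#'   (data.frame: dropped, kept_instead, rho).
#' @export
prune_correlated <- function(table, aucs, rho_max = 0.9) {
  stopifnot(inherits(table, "feature_table"))
  nm <- colnames(table$x)
  stopifnot(all(nm %in% names(aucs)))
  aucs <- aucs[nm]
  cm <- suppressWarnings(abs(stats::cor(table$x)))
  cm[is.na(cm)] <- 0                       # constant columns: no correlation
  cm[lower.tri(cm, diag = TRUE)] <- 0
  pr <- which(cm > rho_max, arr.ind = TRUE)
  alive <- rep(TRUE, length(nm))
  removed <- list()
  if (nrow(pr)) {
    ord <- order(cm[pr], -pmin(pr[, 1], pr[, 2]), decreasing = TRUE)
    pr <- pr[ord, , drop = FALSE]
    for (r in seq_len(nrow(pr))) {
      a <- pr[r, 1]; b <- pr[r, 2]
      if (!alive[a] || !alive[b]) next
      # drop lower AUC; tie -> drop the later column
      drop_b <- aucs[b] < aucs[a] || (aucs[b] == aucs[a] && b > a)
      dr <- if (drop_b) b else a
      kp <- if (drop_b) a else b
      alive[dr] <- FALSE
      removed[[length(removed) + 1L]] <-
        data.frame(dropped = nm[dr], kept_instead = nm[kp],
                   rho = cm[pr[r, 1], pr[r, 2]])
    }
  }
  list(kept = nm[alive],
       removed = if (length(removed)) do.call(rbind, removed) else
         data.frame(dropped = character(0), kept_instead = character(0),
                    rho = numeric(0)))
}

# stratified (by label), grouped (by patient) k-fold assignment.
# returns integer fold id per row; retries seeds when a fold's training
# complement would miss a class.
make_folds <- function(labels, patient_id, k, seed, max_attempts = 10L) {
  groups <- split(seq_along(labels), patient_id)
  glab <- vapply(groups, function(i) max(labels[i]), numeric(1))
  for (att in seq_len(max_attempts)) {
    gfold <- with_seed(seed + att - 1L, {
      gf <- integer(length(groups))
      off <- 0L                # continue the fold cycle across classes so
      for (cl in unique(glab)) {      # few groups still cover every fold
        idx <- which(glab == cl)
        idx <- idx[sample.int(length(idx))]
        gf[idx] <- ((off + seq_along(idx) - 1L) %% k) + 1L
        off <- off + length(idx)
      }
      gf
    })
    fold <- integer(length(labels))
    for (g in seq_along(groups)) fold[groups[[g]]] <- gfold[g]
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(labels[fold != f])) == 2L && any(fold == f), logical(1)))
    if (ok) return(fold)
  }
  stop("could not stratify folds with both classes after ", max_attempts,
       " attempts")
}

# fit the third-order polynomial-kernel SVM used throughout the pipeline.
# features are already min-max normalized, so e1071's internal scaling is off;
# kernel is (u.v + 1)^3 (gamma 1, coef0 1) with box constraint `cost`.
fit_poly_svm <- function(x, y, cost = 1, degree = 3L) {
  e1071::svm(x = x, y = factor(y, levels = c(0L, 1L)),
             kernel = "polynomial", degree = degree, gamma = 1, coef0 = 1,
             cost = cost, scale = FALSE)
}

svm_accuracy <- function(model, x, y) {
  mean(as.integer(as.character(predict(model, x))) == y)
}

# mean train/test accuracy of the SVM over the folds, given feature columns
cv_accuracy <- function(x, labels, fold, cols, cost) {
  k <- max(fold)
  tr <- te <- numeric(k)
  for (f in seq_len(k)) {
    xtr <- x[fold != f, cols, drop = FALSE]
    ytr <- labels[fold != f]
    m <- fit_poly_svm(xtr, ytr, cost = cost)
    tr[f] <- svm_accuracy(m, xtr, ytr)
    te[f] <- svm_accuracy(m, x[fold == f, cols, drop = FALSE],
                          labels[fold == f])
  }
  c(train = mean(tr), test = mean(te))
}

# smallest n at which test accuracy is maximal and not exceeded at n+1, n+2
overfitting_point <- function(test_acc) {
  mx <- max(test_acc)
  cand <- which(test_acc == mx)
  for (n in cand) {
    ahead <- test_acc[seq(n + 1L, length.out = min(2L, length(test_acc) - n))]
    if (all(ahead <= mx)) return(n)
  }
  cand[1L]
}

#' Wrapper feature selection with cross-validated overfitting detection
#'
#' Nested-subset wrapper: for `n = 1..max_n` the top-`n` features by
#' descending AUC are fed to the third-order polynomial SVM (box constraint
#' `C`), evaluated by stratified, patient-grouped k-fold cross-validation.
#' The chosen subset size is the overfitting point: the smallest `n` whose
#' mean test accuracy is maximal and is not exceeded at `n+1` or `n+2` —
#' the point where training accuracy keeps rising while test accuracy stops
#' improving. All randomness is seeded.
#'
#' @param table normalized, pruned [feature_table()].
#' @param ranked_features feature names ordered by descending AUC.
#' @param k_folds number of CV folds (default 4).
#' @param max_n largest subset size to scan (defaults to all ranked
#'   features).
#' @param C box constraint during the scan (default 1).
#' @param svm_degree polynomial degree (default 3).
#' @param seed integer seed for fold assignment.
#' @return An `fs_result`: list with `ranked_features`, `subset_size_n`,
#'   `subset` (chosen names), `train_acc_curve`, `test_acc_curve`, `folds`,
#'   `seed`.
#' @export
wrapper_select <- function(table, ranked_features, k_folds = 4L,
                           max_n = length(ranked_features), C = 1,
                           svm_degree = 3L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"),
            all(ranked_features %in% colnames(table$x)),
            max_n >= 1L, max_n <= length(ranked_features))
  fold <- make_folds(table$labels, table$patient_id, k_folds, seed)
  curves <- vapply(seq_len(max_n), function(n)
    cv_accuracy(table$x, table$labels, fold, ranked_features[seq_len(n)], C),
    numeric(2))
  n_star <- overfitting_point(curves["test", ])
  structure(list(ranked_features = ranked_features,
                 subset_size_n = n_star,
                 subset = ranked_features[seq_len(n_star)],
                 train_acc_curve = unname(curves["train", ]),
                 test_acc_curve = unname(curves["test", ]),
                 folds = fold, seed = seed),
            class = "fs_result")
}

#' @export
print.fs_result <- function(x, ...) {
  cat(sprintf("<fs_result> %d candidate features, chosen subset n = %d\n",
              length(x$ranked_features), x$subset_size_n))
  cat("  subset:", paste(x$subset, collapse = ", "), "\n")
  cat(sprintf("  CV test accuracy at n: %.3f (max over curve %.3f)\n",
              x$test_acc_curve[x$subset_size_n], max(x$test_acc_curve)))
  invisible(x)
}

#' Grid search over the SVM box constraint
#'
#' Evaluates each candidate `C` with the same seeded k-fold CV folds and
#' returns the `C` maximizing mean test accuracy; ties break toward the
#' smallest `C` (stronger regularization).
#'
#' @param table normalized [feature_table()].
#' @param subset feature names to use.
#' @param C_grid candidate box constraints (default 1..50).
#' @param k_folds CV folds (default 4).
#' @param seed integer seed for fold assignment.
#' @return List with `best_C`, `accuracy_curve` (named by C), `folds`.
#' @export
grid_search_C <- function(table, subset, C_grid = 1:50, k_folds = 4L,
                          seed = 1L) {
  stopifnot(inherits(table, "feature_table"), length(subset) >= 1L,
            all(subset %in% colnames(table$x)))
  fold <- make_folds(table$labels, table$patient_id, k_folds, seed)
  acc <- vapply(C_grid, function(C)
    cv_accuracy(table$x, table$labels, fold, subset, C)[["test"]],
    numeric(1))
  names(acc) <- C_grid
  list(best_C = C_grid[which.max(acc)], accuracy_curve = acc, folds = fold)
}
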