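#' Fit the full aggressiveness model on a feature table
#'
#' One-stop fitting function running the complete training stage on a lesion
#' feature table: min-max normalization, per-feature bootstrap AUC ranking,
#' correlation pruning (`|rho| > rho_max` drops the lower-AUC member),
#' AUC-ranked wrapper subset selection with seeded stratified patient-grouped
#' k-fold cross-validation and overfitting-point detection, box-constraint
#' grid search, final polynomial-kernel SVM training with Platt-style score
#' calibration, and Youden / NPV-maximizing cutoff selection on the training
#' scores.
#'
#' @param features numeric matrix or data.frame of named features (one row
#'   per lesion), or a [feature_table()] (then `labels` is ignored).
#' @param labels binary labels: 1 = aggressive (GG > 2).
#' @param patient_id optional patient identifier per row for grouped CV.
#' @param rho_max correlation-pruning threshold (default 0.9).
#' @param k_folds CV folds (default 4).
#' @param C_grid box-constraint grid (default 1..50).
#' @param n_boot bootstrap replicates per feature for AUC ranking.
#' @param band_fraction indeterminate-band width below the Youden cutoff.
#' @param max_n largest wrapper subset size (defaults to all pruned
#'   features).
#' @param seed integer seed driving every random step.
#' @return An object of class `agg_model` with components `scorer`
#'   (`trained_scorer`), `cutoffs` (`cutoff_set`), `fs` (`fs_result`),
#'   `auc_table`, `pruning`, `grid` (C search), `normalization`,
#'   `train_scores`, `labels`, `seed`.
#' @seealso [predict.agg_model()], [summary.agg_model()],
#'   [plot.agg_model()]
#' @export
agg_fit <- function(features, labels = NULL, patient_id = NULL,
                    rho_max = 0.9, k_folds = 4L, C_grid = 1:50,
                    n_boot = 1000L, band_fraction = 0.15, max_n = NULL,
                    seed = 1L) {
  tbl <- if (inherits(features, "feature_table")) features else
    feature_table(features, labels, patient_id)
  if (length(unique(tbl$labels)) < 2L)
    stop("both classes must be present")
  norm <- minmax_fit_apply(tbl)
  ntbl <- norm$table
  auc_tab <- bootstrap_auc_table(ntbl, n_boot = n_boot, seed = seed)
  aucs <- stats::setNames(auc_tab$auc, auc_tab$feature)
  pruning <- prune_correlated(ntbl, aucs, rho_max = rho_max)
  ranked <- pruning$kept[order(aucs[pruning$kept], decreasing = TRUE)]
  if (is.null(max_n)) max_n <- length(ranked)
  fs <- wrapper_select(ntbl, ranked, k_folds = k_folds, max_n = max_n,
                       C = 1, seed = seed)
  grid <- grid_search_C(ntbl, fs$subset, C_grid = C_grid, k_folds = k_folds,
                        seed = seed)
  scorer <- train_scorer(ntbl, fs$subset, C = grid$best_C,
                         normalization = norm$params, seed = seed)
  tr_scores <- score_lesions(scorer, tbl$x)
  yc <- youden_cutoff(tr_scores, tbl$labels)
  nc <- npv_max_cutoff(tr_scores, tbl$labels)
  cuts <- cutoff_set(min(max(as.numeric(yc), 0), 1),
                     min(max(as.numeric(nc), 0), 1),
                     band_fraction = band_fraction)
  structure(list(scorer = scorer, cutoffs = cuts, fs = fs,
                 auc_table = auc_tab, pruning = pruning, grid = grid,
                 normalization = norm$params,
                 train_scores = tr_scores, labels = tbl$labels,
                 seed = as.integer(seed)),
            class = "agg_model")
}

#' @export
print.agg_model <- function(x, ...) {
  cat("Radiomics aggressiveness model (polynomial-kernel SVM)\n")
  cat(sprintf("  features: %d ranked -> %d after pruning -> subset n = %d\n",
              nrow(x$auc_table), length(x$fs$ranked_features),
              x$fs$subset_size_n))
  cat("  subset:", paste(x$fs$subset, collapse = ", "), "\n")
  cat(sprintf("  box constraint C = %d; cutoffs: Youden %.3f, NPV-max %.3f\n",
              as.integer(x$scorer$C), x$cutoffs$youden, x$cutoffs$npv_max))
  invisible(x)
}

#' Summarize a fitted aggressiveness model
#'
#' Reports the selection curves, chosen subset, cutoffs and training-set
#' confusion metrics at both cutoffs.
#'
#' @param object an `agg_model`.
#' @param ... unused.
#' @return Invisibly, a list with the training confusion reports at both
#'   cutoffs and the training AUC.
#' @export
summary.agg_model <- function(object, ...) {
  print(object)
  auc <- auc_mw(object$train_scores, object$labels)
  cat(sprintf("  training AUC: %.3f\n", auc))
  rep_y <- confusion_metrics(object$train_scores, object$labels,
                             object$cutoffs$youden)
  rep_n <- confusion_metrics(object$train_scores, object$labels,
                             object$cutoffs$npv_max)
  cat(sprintf("  at Youden cutoff:  sens %.1f%%, spec %.1f%%\n",
              100 * rep_y$sensitivity, 100 * rep_y$specificity))
  cat(sprintf("  at NPV-max cutoff: sens %.1f%%, NPV %s\n",
              100 * rep_n$sensitivity,
              if (is.na(rep_n$npv)) "undefined" else
                sprintf("%.1f%%", 100 * rep_n$npv)))
  invisible(list(train_auc = auc, youden = rep_y, npv_max = rep_n))
}

#' Selected features of a fitted aggressiveness model
#'
#' @param object an `agg_model`.
#' @param ... unused.
#' @return data.frame of the selected subset with bootstrap AUC and CI, in
#'   ranking order.
#' @export
coef.agg_model <- function(object, ...) {
  at <- object$auc_table
  at[match(object$fs$subset, at$feature), , drop = FALSE]
}

#' Score new lesions with a fitted aggressiveness model
#'
#' @param object an `agg_model`.
#' @param newdata named feature vector, matrix or data.frame (raw feature
#'   scale; the stored normalization is applied). Defaults to refusing —
#'   training scores are available in `object$train_scores`.
#' @param type `"score"` (raw radiomics score), `"level"` (Agg-score band),
#'   `"normalized"` (score minus Youden cutoff) or `"band"` (full
#'   [assign_agg_score()] data.frame).
#' @param ... unused.
#' @return Numeric vector, factor, or data.frame per `type`.
#' @export
predict.agg_model <- function(object, newdata,
                              type = c("score", "level", "normalized",
                                       "band"), ...) {
  type <- match.arg(type)
  s <- score_lesions(object$scorer, newdata)
  if (type == "score") return(s)
  band <- assign_agg_score(s, object$cutoffs)
  switch(type, level = band$level, normalized = band$normalized_score,
         band = band)
}

#' Waterfall plot of the training radiomics scores
#'
#' Bars are training lesions sorted by descending normalized score
#' (score minus the chosen cutoff), coloured by true class; the zero line is
#' the cutoff, so aggressive calls sit above it.
#'
#' @param x an `agg_model`.
#' @param cutoff which cutoff to normalize against: `"npv_max"` (default) or
#'   `"youden"`.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the [waterfall_data()] data.frame.
#' @export
plot.agg_model <- function(x, cutoff = c("npv_max", "youden"), ...) {
  cutoff <- match.arg(cutoff)
  wf <- waterfall_data(x$train_scores, x$labels, x$cutoffs[[cutoff]])
  cols <- ifelse(wf$label == 1L, "firebrick", "steelblue")
  graphics::barplot(wf$normalized_score, col = cols, border = NA,
                    ylab = sprintf("radiomics score - %s cutoff", cutoff),
                    xlab = "lesions (sorted)", ...)
  graphics::abline(h = 0)
  graphics::legend("topright", fill = c("firebrick", "steelblue"),
                   legend = c("aggressive (GG > 2)", "low (GG <= 2)"),
                   bty = "n")
  invisible(wf)
}
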