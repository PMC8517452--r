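# raw polynomial-kernel decision value recomputed from stored support
# vectors: d(x) = sum_i coef_i (gamma x.sv_i + coef0)^degree - rho.
# Kept explicit (rather than predict()) so a scorer serialized to JSON can be
# re-scored without the fitted svm object.
kernel_decision <- function(sv, coefs, rho, gamma, coef0, degree, x) {
  K <- (gamma * (x %*% t(sv)) + coef0)^degree
  as.numeric(K %*% coefs - rho)
}

#' Train the radiomics scoring classifier
#'
#' Fits the third-order polynomial-kernel support vector classifier on the
#' selected feature subset and attaches a monotone Platt-style calibration: a
#' logistic regression of the class label on the (orientation-corrected) SVM
#' decision value, mapping decision values to a radiomics score in `[0, 1]`.
#' Deterministic given the data.
#'
#' @param table min-max normalized [feature_table()] with both classes.
#' @param subset selected feature names.
#' @param C box constraint.
#' @param normalization optional `minmax_params` to store for scoring raw
#'   feature vectors later.
#' @param degree polynomial degree (default 3).
#' @param seed integer seed recorded in the metadata.
#' @return A `trained_scorer`: support vectors, kernel parameters,
#'   calibration coefficients, subset, normalization and metadata.
#' @export
train_scorer <- function(table, subset, C = 1, normalization = NULL,
                         degree = 3L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"),
            all(subset %in% colnames(table$x)))
  if (length(unique(table$labels)) < 2L)
    stop("both classes must be present to train the scorer")
  x <- table$x[, subset, drop = FALSE]
  m <- fit_poly_svm(x, table$labels, cost = C, degree = degree)
  dv <- kernel_decision(m$SV, m$coefs, m$rho, m$gamma, m$coef0, m$degree, x)
  sign <- if (auc_mw(dv, table$labels) >= 0.5) 1 else -1
  dvo <- sign * dv
  cal <- suppressWarnings(
    stats::glm(table$labels ~ dvo, family = stats::binomial()))
  co <- unname(stats::coef(cal))
  scorer <- structure(list(
    subset = subset,
    sv = unname(m$SV), coefs = as.numeric(m$coefs), rho = m$rho,
    gamma = m$gamma, coef0 = m$coef0, degree = as.integer(m$degree),
    sign = sign,
    calibration = list(intercept = co[1], slope = co[2]),
    normalization = normalization,
    C = C, seed = as.integer(seed)), class = "trained_scorer")
  scorer
}

#' Radiomics score of one or more lesions
#'
#' Applies the scorer's stored min-max normalization (when present),
#' restricts to the selected subset, evaluates the polynomial-kernel decision
#' value and maps it through the calibration to `[0, 1]` (clamped). Scoring
#' is deterministic; missing features raise an error naming them.
#'
#' @param model a `trained_scorer`.
#' @param features named numeric vector (one lesion), or a matrix/data.frame
#'   with named columns (one row per lesion).
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
score_lesions <- function(model, features) {
  stopifnot(inherits(model, "trained_scorer"))
  if (is.null(dim(features)))
    features <- matrix(features, nrow = 1,
                       dimnames = list(NULL, names(features)))
  x <- as.matrix(features)
  if (!is.null(model$normalization)) {
    x <- minmax_apply(x, model$normalization)
  }
  miss <- setdiff(model$subset, colnames(x))
  if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
  x <- x[, model$subset, drop = FALSE]
  dv <- model$sign * kernel_decision(model$sv, model$coefs, model$rho,
                                     model$gamma, model$coef0, model$degree, x)
  s <- stats::plogis(model$calibration$intercept +
                       model$calibration$slope * dv)
  pmin(pmax(s, 0), 1)
}

# candidate thresholds: midpoints between adjacent sorted unique scores,
# flanked by one cutoff below all scores and one at the maximum (with the
# strict "positive iff score > cutoff" rule the maximum calls all negative)
candidate_cutoffs <- function(scores) {
  u <- sort(unique(scores))
  mids <- if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  c(u[1] - 1, mids, u[length(u)])
}

confusion_counts <- function(scores, labels, cutoff) {
  pos <- scores > cutoff
  c(tp = sum(pos & labels == 1L), fp = sum(pos & labels == 0L),
    tn = sum(!pos & labels == 0L), fn = sum(!pos & labels == 1L))
}

#' Youden-index cutoff
#'
#' Exhaustive search over the candidate thresholds (midpoints between
#' adjacent sorted unique scores plus the two flanking cutoffs) for the one
#' maximizing Youden's J = sensitivity + specificity - 1, with positives
#' called at `score > cutoff`. Ties break toward higher specificity (the
#' larger cutoff). J is a rank statistic: invariant to strictly monotone
#' transforms of the scores.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = positive).
#' @return The cutoff, with Youden's J as attribute `"J"`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  cand <- candidate_cutoffs(scores)
  J <- vapply(cand, function(c0) {
    cc <- confusion_counts(scores, labels, c0)
    cc[["tp"]] / (cc[["tp"]] + cc[["fn"]]) +
      cc[["tn"]] / (cc[["tn"]] + cc[["fp"]]) - 1
  }, numeric(1))
  best <- which(J == max(J))
  structure(cand[best[length(best)]], J = max(J))   # larger cutoff on ties
}

#' NPV-maximizing cutoff
#'
#' Among candidate thresholds making at least one negative call, returns the
#' one maximizing the negative predictive value; ties break by maximal
#' specificity (most true negatives called) and then by the lower threshold.
#' With distinct continuous training scores this places the cutoff just
#' below the lowest positive score, so NPV = 1 and no aggressive lesion is
#' called negative.
#'
#' @inheritParams youden_cutoff
#' @return The cutoff, with the achieved NPV as attribute `"npv"`.
#' @export
npv_max_cutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  cand <- candidate_cutoffs(scores)
  stats <- vapply(cand, function(c0) {
    cc <- confusion_counts(scores, labels, c0)
    neg <- cc[["tn"]] + cc[["fn"]]
    c(npv = if (neg > 0) cc[["tn"]] / neg else NA_real_,
      spec = cc[["tn"]] / (cc[["tn"]] + cc[["fp"]]))
  }, numeric(2))
  ok <- !is.na(stats["npv", ])
  if (!any(ok)) stop("no threshold yields a negative call")
  cand <- cand[ok]; stats <- stats[, ok, drop = FALSE]
  ord <- order(stats["npv", ], stats["spec", ], -cand, decreasing = TRUE)
  structure(unname(cand[ord[1]]), npv = unname(stats["npv", ord[1]]))
}

#' Cutoff set for aggressiveness banding
#'
#' @param youden Youden-index cutoff on the training scores.
#' @param npv_max NPV-maximizing cutoff.
#' @param band_fraction width of the indeterminate band below the Youden
#'   cutoff, as a fraction of it (default 0.15).
#' @return A `cutoff_set` list.
#' @export
cutoff_set <- function(youden, npv_max, band_fraction = 0.15) {
  stopifnot(youden >= 0, youden <= 1, npv_max >= 0, npv_max <= 1,
            band_fraction > 0, band_fraction < 1)
  structure(list(youden = as.numeric(youden), npv_max = as.numeric(npv_max),
                 band_fraction = band_fraction), class = "cutoff_set")
}

#' Three-level aggressiveness banding of a radiomics score
#'
#' `aggressive` iff the raw score strictly exceeds the Youden cutoff;
#' `indeterminate` iff it lies in `((1 - band_fraction) * youden, youden]`;
#' `indolent` otherwise (score at or below 85 percent of the cutoff with the
#' default band). The banding partitions `[0, 1]` and is monotone in the raw
#' score.
#'
#' @param raw numeric raw score(s) in `[0, 1]`.
#' @param cutoffs a [cutoff_set()].
#' @return An `agg_score` data.frame: `raw_score`, `normalized_score`
#'   (raw minus the Youden cutoff) and `level` (ordered factor
#'   indolent < indeterminate < aggressive).
#' @export
assign_agg_score <- function(raw, cutoffs) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  lo <- (1 - cutoffs$band_fraction) * cutoffs$youden
  level <- ifelse(raw > cutoffs$youden, "aggressive",
                  ifelse(raw > lo, "indeterminate", "indolent"))
  structure(data.frame(raw_score = raw,
                       normalized_score = raw - cutoffs$youden,
                       level = factor(level, levels = c(
                         "indolent", "indeterminate", "aggressive"),
                         ordered = TRUE)),
            class = c("agg_score", "data.frame"))
}

#' Waterfall-plot data for a score set
#'
#' Normalized scores (`score - cutoff`) sorted in descending order with
#' their class labels; the sign of the normalized score equals the
#' aggressive / non-aggressive call at the cutoff.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param cutoff the reference cutoff.
#' @return data.frame with `normalized_score` (descending), `label`.
#' @export
waterfall_data <- function(scores, labels, cutoff) {
  ord <- order(scores, decreasing = TRUE)
  data.frame(normalized_score = scores[ord] - cutoff,
             label = as.integer(labels)[ord])
}
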