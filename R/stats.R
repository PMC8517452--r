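# Wilson score interval for x successes in n trials
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  lo <- if (x == 0) 0 else max(0, ctr - hw)
  hi <- if (x == n) 1 else min(1, ctr + hw)
  c(lo, hi)
}

#' Confusion metrics at a score cutoff
#'
#' Counts at the strict rule `positive iff score > cutoff`, with sensitivity,
#' specificity, PPV, NPV and accuracy as proportions carrying 95 percent
#' Wilson score intervals. A metric whose denominator is zero (no positive or
#' no negative calls) is reported as `NA`, not 0.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = positive class).
#' @param cutoff decision threshold.
#' @return A `confusion_report`: list with `counts` (tp, fp, tn, fn) and the
#'   five proportions, each with a `ci` attribute `c(lo, hi)`.
#' @export
confusion_metrics <- function(scores, labels, cutoff) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  cc <- confusion_counts(scores, labels, cutoff)
  prop <- function(num, den) {
    if (den == 0) return(structure(NA_real_, ci = c(NA_real_, NA_real_)))
    structure(num / den, ci = wilson_ci(num, den))
  }
  structure(list(
    counts = cc,
    sensitivity = prop(cc[["tp"]], cc[["tp"]] + cc[["fn"]]),
    specificity = prop(cc[["tn"]], cc[["tn"]] + cc[["fp"]]),
    ppv = prop(cc[["tp"]], cc[["tp"]] + cc[["fp"]]),
    npv = prop(cc[["tn"]], cc[["tn"]] + cc[["fn"]]),
    accuracy = prop(cc[["tp"]] + cc[["tn"]], sum(cc)),
    cutoff = cutoff), class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cc <- x$counts
  fmt <- function(name, v, num, den) {
    if (is.na(v)) return(sprintf("  %-12s undefined (no calls)\n", name))
    ci <- attr(v, "ci")
    sprintf("  %-12s %5.1f%% [%d/%d] (%.1f-%.1f)\n", name, 100 * v, num, den,
            100 * ci[1], 100 * ci[2])
  }
  cat(sprintf("Confusion report at cutoff %.4g\n", x$cutoff))
  cat(fmt("sensitivity", x$sensitivity, cc[["tp"]], cc[["tp"]] + cc[["fn"]]))
  cat(fmt("specificity", x$specificity, cc[["tn"]], cc[["tn"]] + cc[["fp"]]))
  cat(fmt("PPV", x$ppv, cc[["tp"]], cc[["tp"]] + cc[["fp"]]))
  cat(fmt("NPV", x$npv, cc[["tn"]], cc[["tn"]] + cc[["fn"]]))
  cat(fmt("accuracy", x$accuracy, cc[["tp"]] + cc[["tn"]], sum(cc)))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided test that the two samples come from the same distribution.
#' For small samples (both sizes <= `exact_max`) the null distribution of U
#' is enumerated exactly over all group assignments of the pooled values
#' (valid with ties); otherwise the tie-corrected normal approximation is
#' used. The statistic U counts pairs where `a` exceeds `b`, ties counting
#' one half.
#'
#' @param a,b numeric samples.
#' @param exact_max per-sample size limit for exact enumeration (default 8).
#' @return List with `U` (for sample `a`) and `p`.
#' @export
mann_whitney <- function(a, b, exact_max = 8L) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= U + 1e-9), mean(u_all >= U - 1e-9)))
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    n <- n1 + n2
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(list(U = U, p = 1))
    z <- (U - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p = p)
}

#' DeLong comparison of two paired AUCs
#'
#' Compares the AUCs of two score vectors over the same cases using DeLong's
#' covariance estimate for paired ROC curves and a two-sided z-test on the
#' AUC difference. A degenerate zero-variance difference (e.g. identical
#' scores) returns p = 1.
#'
#' @param scores1,scores2 paired score vectors.
#' @param labels binary labels (1 = positive).
#' @return List with `auc1`, `auc2`, `p`.
#' @export
delong_test <- function(scores1, scores2, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores1) == length(labels),
            length(scores2) == length(labels))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  r1 <- pROC::roc(labels, scores1, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  r2 <- pROC::roc(labels, scores2, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  auc1 <- as.numeric(pROC::auc(r1))
  auc2 <- as.numeric(pROC::auc(r2))
  p <- tryCatch({
    tst <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
    as.numeric(tst$p.value)
  }, error = function(e) NA_real_)
  if (!is.finite(p)) p <- 1
  list(auc1 = auc1, auc2 = auc2, p = p)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Without continuity correction by default (set `yates = TRUE` for the
#' corrected statistic). A zero row or column marginal is a degenerate table
#' and raises an error.
#'
#' @param counts 2x2 matrix of nonnegative integer counts.
#' @param yates apply Yates continuity correction.
#' @return List with `statistic`, `p`.
#' @export
chi_squared_2x2 <- function(counts, yates = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 2L)), all(counts >= 0),
            all(counts == round(counts)))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: zero marginal")
  tst <- suppressWarnings(stats::chisq.test(counts, correct = yates))
  list(statistic = unname(tst$statistic), p = unname(tst$p.value))
}
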