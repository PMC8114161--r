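## Pooled classification metrics and closed-form baseline expectations.

#' Pooled classification metrics across outer folds
#'
#' Predictions from all outer folds are pooled before any metric is
#' computed (per-fold metrics are undefined for single-row folds).
#' Classes default to thresholding the predicted probability at 0.5.
#' Per-class F1 is defined as 0 when the class is never predicted or
#' never occurs; macro F1 is the unweighted mean of the two per-class
#' F1 scores.  AUC is the rank (Mann-Whitney) statistic of the pooled
#' probabilities.  All values are percentages rounded to one decimal.
#'
#' @param y_true Pooled true labels (0/1).
#' @param prob Pooled predicted probabilities of class 1.
#' @param class Optional explicit class predictions (for classifiers,
#'   like the random-weighted baseline, whose class draw is not a
#'   probability threshold).
#' @return Named list: `accuracy`, `precision_0`, `recall_0`, `f1_0`,
#'   `precision_1`, `recall_1`, `f1_1`, `macro_f1`, `auc`.
#' @export
pooled_metrics <- function(y_true, prob, class = NULL) {
  y_true <- as.integer(y_true)
  if (is.null(class)) class <- as.integer(prob > 0.5)
  class <- as.integer(class)
  stopifnot(length(y_true) == length(class), length(prob) == length(y_true))
  prf <- function(c) {
    tp <- sum(class == c & y_true == c)
    prec <- if (sum(class == c) > 0) tp / sum(class == c) else 0
    rec <- if (sum(y_true == c) > 0) tp / sum(y_true == c) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1)
  }
  m0 <- prf(0L); m1 <- prf(1L)
  n1 <- as.numeric(sum(y_true == 1L)); n0 <- as.numeric(sum(y_true == 0L))
  auc <- if (n0 > 0 && n1 > 0) {
    r <- rank(prob)
    (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  } else NA_real_
  pc <- function(x) round(100 * x, 1)
  list(accuracy = pc(mean(class == y_true)),
       precision_0 = pc(m0[1]), recall_0 = pc(m0[2]), f1_0 = pc(m0[3]),
       precision_1 = pc(m1[1]), recall_1 = pc(m1[2]), f1_1 = pc(m1[3]),
       macro_f1 = pc((m0[3] + m1[3]) / 2), auc = pc(auc))
}

#' Closed-form baseline metrics at a given class-0 prevalence
#'
#' Expected metric panels for the two label-only baselines, as functions
#' of the class-0 prevalence `p` alone.  Majority classifier (always
#' predicts 0 when p >= 0.5): accuracy = p, precision_0 = p,
#' recall_0 = 1, f1_0 = 2p/(1+p), all class-1 metrics 0,
#' macro F1 = p/(1+p), AUC = 1/2.  Random weighted classifier
#' (predicts class c with its training prevalence, independent of
#' features): expected precision_c = recall_c = f1_c = prevalence of c,
#' accuracy = p^2 + (1-p)^2, macro F1 = 1/2, AUC = 1/2.
#'
#' @param p Class-0 prevalence, in \[0.5, 1\] for the majority formulas
#'   to describe the always-0 classifier.
#' @return List of two metric panels (`majority`, `random_weighted`) in
#'   the same percentage format as [pooled_metrics()].
#' @export
analytic_baseline_metrics <- function(p) {
  stopifnot(p >= 0, p <= 1)
  pc <- function(x) round(100 * x, 1)
  majority <- list(
    accuracy = pc(p), precision_0 = pc(p), recall_0 = pc(1),
    f1_0 = pc(2 * p / (1 + p)), precision_1 = pc(0), recall_1 = pc(0),
    f1_1 = pc(0), macro_f1 = pc(p / (1 + p)), auc = pc(0.5)
  )
  q <- 1 - p
  random_weighted <- list(
    accuracy = pc(p^2 + q^2), precision_0 = pc(p), recall_0 = pc(p),
    f1_0 = pc(p), precision_1 = pc(q), recall_1 = pc(q), f1_1 = pc(q),
    macro_f1 = pc(0.5), auc = pc(0.5)
  )
  list(majority = majority, random_weighted = random_weighted)
}
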