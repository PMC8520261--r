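# Split protocol, confusion metrics, ROC/AUC and the rank-sum model
# comparison used to evaluate the network against its ablations.

#' Repeated stratified 8:1:1 splits
#'
#' For each repeat the items are stratified by label into ten random folds;
#' eight folds train, one validates, one tests. Across the default 30
#' repeats every item is expected to appear about 24/3/3 times in the
#' train/validation/test roles. Deterministic given \code{seed}.
#'
#' @param labels vector of item labels (used for stratification).
#' @param n_repeats number of random splits (default 30).
#' @param n_folds number of folds (default 10, giving the 8:1:1 ratio).
#' @param seed RNG seed.
#' @return list of class \code{SplitPlan}; each element has integer index
#'   vectors \code{train}, \code{val}, \code{test}.
#' @export
makeRandomSplits <- function(labels, n_repeats = 30L, n_folds = 10L, seed = 1L) {
  n <- length(labels)
  if (n < n_folds) stop("need at least ", n_folds, " items")
  .withSeed(seed, {
    plan <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      fold <- integer(n)
      for (lv in unique(labels)) {
        idx <- which(labels == lv)
        fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
      vt <- sample.int(n_folds, 2L)
      plan[[r]] <- list(train = which(!fold %in% vt),
                        val = which(fold == vt[1]),
                        test = which(fold == vt[2]))
    }
    structure(plan, class = "SplitPlan", n_items = n)
  })
}

#' Confusion-matrix metrics at a decision threshold
#'
#' Counts and the five standard ratios: sensitivity (recall) TP/(TP+FN),
#' specificity TN/(TN+FP), accuracy (TP+TN)/total, precision TP/(TP+FP)
#' and F1 = 2 * precision * recall / (precision + recall). Ratios with a
#' zero denominator are reported as NA (undefined), never as 0.
#'
#' @param labels 0/1 or "negative"/"positive" vector.
#' @param scores positive-class probabilities or scores.
#' @param threshold decision boundary (default 0.5).
#' @return named list of counts and ratios.
#' @export
confusionMetrics <- function(labels, scores, threshold = 0.5) {
  y <- .labels01(labels)
  if (length(y) != length(scores)) stop("labels and scores differ in length")
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- rat(tp, tp + fp); recall <- rat(tp, tp + fn)
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       sensitivity = recall, specificity = rat(tn, tn + fp),
       accuracy = rat(tp + tn, tp + fp + tn + fn),
       precision = precision, F1 = f1Score(precision, recall))
}

#' F1 score from precision and recall
#'
#' @param precision,recall the two ratios.
#' @return 2 * precision * recall / (precision + recall); NA when undefined.
#' @examples
#' f1Score(0.887, 0.830)
#' @export
f1Score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall) || precision + recall == 0)
    return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores to trace
#' (1 - specificity, sensitivity) points, and computes the AUC by the
#' rank-based (Mann-Whitney) formulation with midrank tie correction,
#' which equals trapezoidal integration of the curve.
#'
#' @param labels 0/1 or "negative"/"positive" vector (both classes
#'   required).
#' @param scores numeric scores, larger = more positive.
#' @return list of class \code{pirbindROC} with \code{points} (data.frame
#'   threshold/fpr/tpr) and \code{auc}.
#' @export
rocAuc <- function(labels, scores) {
  y <- .labels01(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (length(y) != length(scores)) stop("labels and scores differ in length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- (sum(rank(scores)[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    tpr[i] <- sum(scores >= thr[i] & y == 1) / n1
    fpr[i] <- sum(scores >= thr[i] & y == 0) / n0
  }
  structure(list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc), class = "pirbindROC")
}

#' @export
print.pirbindROC <- function(x, ...) {
  cat("ROC with", nrow(x$points), "points; AUC =", round(x$auc, 4), "\n")
  invisible(x)
}

#' One-tailed rank-sum comparison of AUC lists
#'
#' Wilcoxon rank-sum (Mann-Whitney) test of the hypothesis that the values
#' in \code{a} are stochastically larger than those in \code{b}, using the
#' normal approximation with midrank tie correction (identical samples give
#' p = 0.5).
#'
#' @param auc_a,auc_b per-repeat AUC vectors (length >= 2 each).
#' @return the one-tailed p-value for a > b.
#' @export
compareAucRanksum <- function(auc_a, auc_b) {
  if (length(auc_a) < 2 || length(auc_b) < 2)
    stop("need at least 2 values per group")
  stats::wilcox.test(auc_a, auc_b, alternative = "greater", exact = FALSE,
                     correct = FALSE)$p.value
}

#' Evaluate a model on a pair table
#'
#' @param model a trained \linkS4class{PiRBindModel}.
#' @param pairs labeled pair data.frame.
#' @param threshold decision boundary for the confusion metrics.
#' @return list with \code{metrics} (see \code{\link{confusionMetrics}}),
#'   \code{roc} and \code{auc}.
#' @export
evaluateModel <- function(model, pairs, threshold = 0.5) {
  p <- predictPairs(model, pairs)
  roc <- rocAuc(pairs$label, p)
  list(metrics = confusionMetrics(pairs$label, p, threshold), roc = roc,
       auc = roc$auc)
}
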