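# ROC and precision-recall surfaces. The ROC sweep groups tied scores at a
# single threshold and integrates by trapezoid, which makes the AUC equal
# to the rank-sum probability-of-correct-ordering with ties counted one
# half. auPR uses interpolation-free step-wise summation, sum over
# thresholds of (R_i - R_{i-1}) * P_i — linear PR interpolation would
# overestimate.

.check_scored <- function(scores, labels) {
  if (length(scores) != length(labels) || length(scores) < 1L)
    stop("scores and labels must be equal-length, non-empty")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
}

#' ROC curve and AUC
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels 0/1 truth labels; both classes must be present.
#' @return list with `fpr`, `tpr`, `thresholds` (descending; ties grouped)
#'   and `auc` (trapezoid rule).
#' @export
roc_curve <- function(scores, labels) {
  .check_scored(scores, labels)
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L) stop("ROC requires both classes")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  last <- cumsum(rle(s)$lengths)          # last index of each tied block
  tp <- cumsum(y)[last]; fp <- (seq_along(y) - cumsum(y))[last]
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, s[last]), auc = auc)
}

#' Precision-recall curve and auPR
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 truth labels; at least one positive required.
#' @return list with `recall`, `precision` (descending-score sweep, ties
#'   grouped) and `aupr` by step-wise summation.
#' @export
pr_curve <- function(scores, labels) {
  .check_scored(scores, labels)
  P <- sum(labels == 1L)
  if (P == 0L) stop("PR requires at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]
  recall <- tp / P
  precision <- tp / last
  aupr <- sum(diff(c(0, recall)) * precision)
  list(recall = recall, precision = precision, aupr = aupr)
}

#' Stratified cross-validated classification performance
#'
#' Stratified fold assignment (seeded from the config seed), one forest
#' retrained per fold, held-out samples scored by the fraction of trees
#' voting accessible.
#'
#' @param fm a `FeatureMatrix` with both classes.
#' @param config a [forest_config()]; the fold-b model trains with seed
#'   `config$seed + b` so folds are independent but reproducible.
#' @param n_folds number of folds (>= 2).
#' @return list with per-fold `auc` and `aupr` vectors, their means, and
#'   the fold assignment.
#' @export
cross_validated_auc <- function(fm, config = forest_config(), n_folds = 5L) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  y <- fm$labels
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < n_folds)
      stop("class ", cls, " has fewer samples than folds")
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  auc <- numeric(n_folds); aupr <- numeric(n_folds)
  for (b in seq_len(n_folds)) {
    test <- which(fold == b); train <- which(fold != b)
    if (length(unique(y[test])) < 2L || length(unique(y[train])) < 2L)
      stop("fold ", b, " lacks one of the classes")
    cfg <- config; cfg$seed <- config$seed + b
    model <- train_forest(subset_samples(fm, train), cfg)
    sc <- predict_forest(model, subset_samples(fm, test))$score
    auc[b] <- roc_curve(sc, y[test])$auc
    aupr[b] <- pr_curve(sc, y[test])$aupr
  }
  list(auc = auc, aupr = aupr, mean_auc = mean(auc), mean_aupr = mean(aupr),
       fold = fold)
}
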