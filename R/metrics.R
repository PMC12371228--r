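#' ROC curve and AUC
#'
#' AUC is the probability that a randomly chosen positive sample outscores a
#' randomly chosen negative one, with ties counting one half (the rank-sum
#' form, equivalent to trapezoidal integration of the ROC curve).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (factor `pN0`/`pN+`, logical, or 0/1).
#' @return list with `roc` (data.frame of `fpr`, `tpr` at every threshold)
#'   and `auc`.
#' @export
rocAuc <- function(scores, labels) {
  pos <- asPositive(labels)
  keep <- !is.na(pos) & !is.na(scores)
  scores <- scores[keep]; pos <- pos[keep]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(-scores)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  last <- !duplicated(scores[ord], fromLast = TRUE)  # one point per threshold
  roc <- data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
  list(roc = roc, auc = auc)
}

#' Balanced accuracy
#'
#' `(sensitivity + specificity) / 2` for hard class predictions. Probability
#' scores upstream are thresholded at 0.5.
#'
#' @param predicted predicted binary labels (same encodings as `labels`).
#' @param labels true binary labels; both classes must be present.
#' @return balanced accuracy in `[0, 1]`.
#' @export
balancedAccuracy <- function(predicted, labels) {
  truth <- asPositive(labels)
  pred <- asPositive(predicted)
  stopifnot(length(pred) == length(truth))
  if (!any(truth) || all(truth)) stop("both classes must be present")
  sens <- mean(pred[truth])
  spec <- mean(!pred[!truth])
  (sens + spec) / 2
}

# Stratified fold assignment: within each class, shuffled indices receive
# fold ids from a shuffled cyclic sequence, keeping per-fold class counts
# within one sample of proportionality.
stratifiedFolds <- function(pos, k) {
  fold <- integer(length(pos))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(pos == cls)
    if (length(idx) == 0) next
    fold[sample(idx)] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Build a repeated stratified nested fold plan
#'
#' Assigns samples to `repeats` x `kOuter` outer folds and each outer
#' training set to `kInner` inner folds, stratified by class. The plan is
#' fully determined by the seed, so different signatures and feature
#' selection methods can be evaluated on identical (predefined) partitions.
#'
#' @param labels binary labels (factor `pN0`/`pN+`, logical, or 0/1); `NA`
#'   labels are not allowed (exclude unlabelled samples first).
#' @param kOuter outer folds (default 5).
#' @param kInner inner folds (default 5).
#' @param repeats repeats (default 1; 10 repeats x 5 folds gives the
#'   50-outer-fold protocol).
#' @param seed integer seed.
#' @param sampleIds optional sample identifiers (default names of `labels`
#'   or indices).
#' @return a [FoldPlan-class].
#' @export
makeFoldPlan <- function(labels, kOuter = 5, kInner = 5, repeats = 1,
                         seed = 1, sampleIds = NULL) {
  pos <- asPositive(labels)
  if (anyNA(pos)) stop("labels must not contain NA")
  n <- length(pos)
  if (min(sum(pos), sum(!pos)) < kOuter)
    stop("each class needs at least kOuter samples")
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(names(labels))) names(labels)
                 else as.character(seq_len(n))
  outer <- matrix(0L, n, repeats, dimnames = list(sampleIds, NULL))
  inner <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    outer[, r] <- withSeed(deriveSeed(seed, "outer", r),
                           stratifiedFolds(pos, kOuter))
    inner[[r]] <- vector("list", kOuter)
    for (f in seq_len(kOuter)) {
      train <- which(outer[, r] != f)
      inner[[r]][[f]] <- withSeed(
        deriveSeed(seed, "inner", r, f),
        setNames(stratifiedFolds(pos[train], kInner), sampleIds[train]))
    }
  }
  new("FoldPlan", repeats = as.integer(repeats), kOuter = as.integer(kOuter),
      kInner = as.integer(kInner), sampleIds = sampleIds, outer = outer,
      inner = inner, seed = as.integer(seed))
}
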