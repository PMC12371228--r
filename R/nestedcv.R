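# Shared engine behind nestedCvEvaluate / leakyEvaluate. When
# `fixedFeatures` is non-NULL, per-fold selection is skipped (either a fixed
# signature, or — the leaky contrast — features pre-selected on the full
# dataset).
runCvLoop <- function(m, pos, spec, plan, fsMethod, k, seed, fixedFeatures,
                      leaky, fsLabel) {
  rows <- list()
  skipped <- 0L
  for (r in seq_len(plan@repeats)) {
    for (f in seq_len(plan@kOuter)) {
      train <- which(plan@outer[, r] != f)
      test <- which(plan@outer[, r] == f)
      if (length(unique(pos[test])) < 2) {
        skipped <- skipped + 1L
        next
      }
      feats <- if (!is.null(fixedFeatures)) fixedFeatures
      else selectFeatures(m[, train, drop = FALSE], pos[train],
                          method = fsMethod, k = k,
                          seed = deriveSeed(seed, "fs", r, f), spec = spec,
                          innerFoldIds = unname(plan@inner[[r]][[f]]))
      feats <- intersect(feats, rownames(m))
      fit <- fitModel(m[feats, train, drop = FALSE], pos[train], spec = spec,
                      innerFoldIds = unname(plan@inner[[r]][[f]]),
                      seed = deriveSeed(seed, "fit", r, f))
      pr <- predictFit(fit, m[feats, test, drop = FALSE])
      auc <- if (fit@degenerate) 0.5 else rocAuc(pr, pos[test])$auc
      ba <- balancedAccuracy(pr >= 0.5, pos[test])
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = r, outer_fold = f, auc = auc, balanced_accuracy = ba,
        n_features_selected = length(fit@selectedFeatures),
        degenerate = fit@degenerate, stringsAsFactors = FALSE)
      rows[[length(rows)]]$selected_features <- list(fit@selectedFeatures)
    }
  }
  per.fold <- do.call(rbind, rows)
  new("CVResult", perFold = per.fold,
      meanAuc = mean(per.fold$auc), sdAuc = sd(per.fold$auc),
      meanBalancedAccuracy = mean(per.fold$balanced_accuracy),
      degenerateFolds = sum(per.fold$degenerate),
      skippedFolds = skipped, leaky = leaky, fsMethod = fsLabel)
}

# Resolve (matrix, positive-class vector) from cohort + labels, dropping
# unlabelled samples, and check the plan covers them.
cvInputs <- function(x, labels, plan) {
  m <- if (is(x, "NodeCohort")) exprs2(x) else as.matrix(x)
  if (is.null(labels) && is(x, "NodeCohort")) labels <- nodeStatus(x)
  if (is.null(labels)) stop("labels required")
  pos <- asPositive(labels)
  keep <- !is.na(pos)
  m <- m[, keep, drop = FALSE]
  pos <- pos[keep]
  if (!is.null(plan)) {
    if (nrow(plan@outer) != ncol(m) ||
        !identical(rownames(plan@outer), colnames(m)))
      stop("fold plan does not cover exactly the labelled samples")
  }
  list(m = m, pos = pos)
}

#' Leakage-free repeated nested cross-validation
#'
#' For every (repeat, outer fold): feature selection (or restriction to a
#' fixed signature), standardisation, and hyperparameter tuning run strictly
#' inside the outer training set, using that fold's predefined inner folds;
#' the model then predicts the untouched outer test fold. The outer test
#' fold never influences centering, standardisation, selection or tuning.
#' Outer folds whose test set contains a single class are skipped and
#' counted. Degenerate folds (tuned model kept zero features) are reported
#' with AUC 0.5 and flagged rather than dropped, so aggregates stay
#' well-defined; `strict = TRUE` drops them instead.
#'
#' @param x expression matrix (genes x samples) or labelled [NodeCohort].
#' @param labels binary labels (default `nodeStatus(x)`).
#' @param spec a [modelSpec].
#' @param plan a [FoldPlan-class] over the labelled samples.
#' @param fsMethod feature-selection method (see [selectFeatures]); ignored
#'   when `signature` is given.
#' @param signature fixed feature set: a [GeneSignature-class] or character
#'   vector of genes (evaluated as-is, no selection).
#' @param k number of genes for `t_test` / `wilcoxon` / `rf_importance`
#'   selection (default 100).
#' @param seed RNG seed for per-fold selection and fitting substreams.
#' @param strict drop degenerate folds from the aggregates (default FALSE).
#' @return a [CVResult-class] with `leaky = FALSE`.
#' @export
nestedCvEvaluate <- function(x, labels = NULL, spec = modelSpec(), plan,
                             fsMethod = "t_test", signature = NULL, k = 100,
                             seed = 1, strict = FALSE) {
  inp <- cvInputs(x, labels, plan)
  fixed <- NULL
  lab <- fsMethod
  if (!is.null(signature)) {
    genes <- if (is(signature, "GeneSignature")) signature@genes
             else as.character(signature)
    fixed <- intersect(genes, rownames(inp$m))
    if (length(fixed) == 0) stop("signature not representable in dataset")
    lab <- "fixed_signature"
  }
  res <- runCvLoop(inp$m, inp$pos, spec, plan, fsMethod, k, seed, fixed,
                   leaky = FALSE, fsLabel = lab)
  if (strict && res@degenerateFolds > 0) {
    keep <- !res@perFold$degenerate
    res@perFold <- res@perFold[keep, , drop = FALSE]
    res@meanAuc <- mean(res@perFold$auc)
    res@sdAuc <- sd(res@perFold$auc)
    res@meanBalancedAccuracy <- mean(res@perFold$balanced_accuracy)
  }
  res
}

#' Deliberately leaky cross-validation (selection-bias contrast)
#'
#' Identical protocol to [nestedCvEvaluate] except that feature selection is
#' run ONCE on the full dataset — labels included — before cross-validation.
#' On data with no true signal this inflates the apparent AUC well above
#' 0.5; the gap to the nested estimate measures the information leakage.
#'
#' @inheritParams nestedCvEvaluate
#' @return a [CVResult-class] with `leaky = TRUE`.
#' @export
leakyEvaluate <- function(x, labels = NULL, spec = modelSpec(), plan,
                          fsMethod = "t_test", k = 100, seed = 1) {
  inp <- cvInputs(x, labels, plan)
  feats <- selectFeatures(inp$m, inp$pos, method = fsMethod, k = k,
                          seed = deriveSeed(seed, "leakyfs"), spec = spec)
  runCvLoop(inp$m, inp$pos, spec, plan, fsMethod, k, seed, feats,
            leaky = TRUE, fsLabel = fsMethod)
}

#' Train a final model on one cohort and apply it to another
#'
#' Feature selection and tuning use the ENTIRE training cohort (the
#' full-data protocol whose apparent performance the nested estimate is
#' meant to audit). Reported are the apparent (training-cohort) AUC and the
#' external AUC on the untouched test cohort. All per-gene standardisation
#' parameters come from the training cohort only; the gene universe is the
#' intersection of the two cohorts (a warning fires when under half of the
#' selected features survive the intersection).
#'
#' @param train,test labelled [NodeCohort]s (or matrices plus
#'   `trainLabels` / `testLabels`).
#' @param trainLabels,testLabels labels when matrices are given.
#' @param spec a [modelSpec].
#' @param fsMethod feature-selection method, or `NULL` with `signature`.
#' @param signature optional fixed feature set.
#' @param k selection size (default 100).
#' @param kInner inner folds for tuning (default 5).
#' @param seed RNG seed.
#' @return list with `fit` ([FitResult-class]), `trainingAuc`, `externalAuc`,
#'   and `genesUsed`.
#' @export
trainFinalAndApply <- function(train, test, trainLabels = NULL,
                               testLabels = NULL, spec = modelSpec(),
                               fsMethod = "t_test", signature = NULL,
                               k = 100, kInner = 5, seed = 1) {
  tr <- cvInputs(train, trainLabels, NULL)
  te <- cvInputs(test, testLabels, NULL)
  shared <- intersect(rownames(tr$m), rownames(te$m))
  if (length(shared) == 0) stop("cohorts share no genes")
  message("cohorts share ", length(shared), " genes")
  mtr <- tr$m[shared, , drop = FALSE]
  mte <- te$m[shared, , drop = FALSE]
  if (!is.null(signature)) {
    genes <- if (is(signature, "GeneSignature")) signature@genes
             else as.character(signature)
    feats <- intersect(genes, shared)
    if (length(feats) == 0) stop("signature not representable in both cohorts")
  } else {
    inner <- withSeed(deriveSeed(seed, "finalfolds"),
                      stratifiedFolds(tr$pos, kInner))
    feats <- selectFeatures(mtr, tr$pos, method = fsMethod, k = k,
                            seed = deriveSeed(seed, "finalfs"), spec = spec,
                            innerFoldIds = inner)
    lost <- setdiff(feats, shared)
    if (length(lost) > length(feats) / 2)
      warning("gene intersection covers under half of the selected features")
    feats <- intersect(feats, shared)
  }
  inner <- withSeed(deriveSeed(seed, "finalfolds"),
                    stratifiedFolds(tr$pos, kInner))
  fit <- fitModel(mtr[feats, , drop = FALSE], tr$pos, spec = spec,
                  innerFoldIds = inner, seed = deriveSeed(seed, "finalfit"))
  ext.pr <- predictFit(fit, mte[feats, , drop = FALSE])
  external <- if (fit@degenerate) 0.5 else rocAuc(ext.pr, te$pos)$auc
  list(fit = fit, trainingAuc = fit@trainingAuc, externalAuc = external,
       genesUsed = feats)
}
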