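#' Model and tuning specification
#'
#' @param family `"elastic_net_logistic"` (default) or `"random_forest"`.
#' @param alphaGrid elastic-net mixing values tried in the inner folds
#'   (default 0 to 1 in 0.05 increments).
#' @param nLambda length of the per-alpha penalty path (default 100).
#' @param lambdaMinRatio smallest lambda as a fraction of the
#'   all-coefficients-zero lambda (default 1e-4).
#' @param rfNumTrees random-forest trees (default 500).
#' @param rfMtry variables per split (default `floor(sqrt(p))`).
#' @param standardize standardise features to training-fold mean/SD before
#'   fitting, re-applying the same transform at prediction time (default
#'   TRUE).
#' @param tuneMetric inner-fold model-selection criterion: `"auc"` (default,
#'   matching the reporting metric) or `"deviance"`.
#' @param importance random-forest importance mode for feature selection:
#'   `"permutation"` (default) or `"impurity"`.
#' @return list of class `ModelSpec`.
#' @export
modelSpec <- function(family = c("elastic_net_logistic", "random_forest"),
                      alphaGrid = seq(0, 1, by = 0.05), nLambda = 100,
                      lambdaMinRatio = 1e-4, rfNumTrees = 500, rfMtry = NULL,
                      standardize = TRUE, tuneMetric = c("auc", "deviance"),
                      importance = c("permutation", "impurity")) {
  spec <- list(family = match.arg(family), alphaGrid = alphaGrid,
               nLambda = nLambda, lambdaMinRatio = lambdaMinRatio,
               rfNumTrees = rfNumTrees, rfMtry = rfMtry,
               standardize = isTRUE(standardize),
               tuneMetric = match.arg(tuneMetric),
               importance = match.arg(importance))
  stopifnot(all(spec$alphaGrid >= 0 & spec$alphaGrid <= 1),
            spec$rfNumTrees >= 1)
  class(spec) <- c("ModelSpec", "list")
  spec
}

# Vectorised two-group pooled-variance t-test p-values (genes x samples).
# Genes with zero pooled variance and zero mean difference (constants) get
# NA so they rank last.
rowTTestP <- function(m, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  m1 <- rowMeans(m[, pos, drop = FALSE])
  m0 <- rowMeans(m[, !pos, drop = FALSE])
  ss <- rowSums((m[, pos, drop = FALSE] - m1)^2) +
    rowSums((m[, !pos, drop = FALSE] - m0)^2)
  d <- n1 + n0 - 2
  se <- sqrt(ss / d * (1 / n1 + 1 / n0))
  t <- (m1 - m0) / se
  p <- 2 * pt(-abs(t), df = d)
  p[se == 0 & (m1 - m0) != 0] <- 0
  p[se == 0 & (m1 - m0) == 0] <- NA
  p
}

# Vectorised two-group Wilcoxon rank-sum p-values (normal approximation with
# tie correction). All-tied genes get NA so they rank last.
rowWilcoxonP <- function(m, pos) {
  n1 <- sum(pos); n0 <- sum(!pos); n <- n1 + n0
  apply(m, 1, function(v) {
    r <- rank(v)
    W <- sum(r[pos]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    tie.term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n0 / 12 * (n + 1 - tie.term)
    if (sigma2 <= 0) return(NA_real_)
    z <- (W - n1 * n0 / 2) / sqrt(sigma2)
    2 * pnorm(-abs(z))
  })
}

#' Select candidate features on training data
#'
#' Ranks genes on the training data only (the nested engine guarantees the
#' outer test fold never reaches this function) and returns the top `k` by:
#' `t_test` / `wilcoxon` — smallest two-group p-value (constant genes have an
#' undefined statistic and rank last); `rf_importance` — largest
#' random-forest variable importance; `embedded_enet` — the nonzero
#' coefficients of the inner-CV-tuned elastic net (no fixed `k`).
#'
#' @param x training expression matrix (genes x samples) or [NodeCohort].
#' @param labels binary labels for the training samples.
#' @param method one of `"t_test"`, `"wilcoxon"`, `"rf_importance"`,
#'   `"embedded_enet"`.
#' @param k number of genes to keep (ignored by `embedded_enet`).
#' @param seed RNG seed (random forest and elastic-net inner folds).
#' @param spec a [modelSpec] (forest size, alpha grid, ...).
#' @param innerFoldIds optional inner-fold assignment for `embedded_enet`;
#'   generated from `seed` when absent.
#' @return character vector of selected gene symbols.
#' @export
selectFeatures <- function(x, labels, method = c("t_test", "wilcoxon",
                                                 "rf_importance",
                                                 "embedded_enet"),
                           k = 100, seed = 1, spec = modelSpec(),
                           innerFoldIds = NULL) {
  method <- match.arg(method)
  m <- if (is(x, "NodeCohort")) exprs2(x) else as.matrix(x)
  pos <- asPositive(labels)
  stopifnot(!anyNA(pos), ncol(m) == length(pos))
  if (method != "embedded_enet" && k > nrow(m))
    stop("k exceeds the number of genes")
  if (method %in% c("t_test", "wilcoxon")) {
    p <- if (method == "t_test") rowTTestP(m, pos) else rowWilcoxonP(m, pos)
    ord <- order(p, rownames(m), na.last = TRUE)
    return(rownames(m)[ord][seq_len(k)])
  }
  if (method == "rf_importance") {
    fit <- ranger::ranger(x = t(m), y = factor(pos),
                          num.trees = spec$rfNumTrees,
                          importance = spec$importance, seed = seed,
                          num.threads = 1)
    imp <- fit$variable.importance
    ord <- order(-imp, names(imp))
    return(names(imp)[ord][seq_len(k)])
  }
  # embedded_enet
  if (is.null(innerFoldIds))
    innerFoldIds <- withSeed(deriveSeed(seed, "fsfolds"),
                             stratifiedFolds(pos, 5))
  std <- standardizeTrain(m, spec$standardize)
  tuned <- tuneEnet(t(std$x), pos, spec, innerFoldIds)
  tuned$selected
}

# Training-fold standardisation; sd-zero features get scale 1.
standardizeTrain <- function(m, standardize) {
  if (!standardize)
    return(list(x = m, center = setNames(rep(0, nrow(m)), rownames(m)),
                scale = setNames(rep(1, nrow(m)), rownames(m))))
  ctr <- rowMeans(m)
  sc <- apply(m, 1, sd)
  sc[sc == 0] <- 1
  list(x = (m - ctr) / sc, center = ctr, scale = sc)
}

# Inner-fold grid search over (alpha, lambda). X is samples x features
# (already standardised), y logical. Returns the refit on the full training
# data at the winning pair plus the nonzero feature set.
tuneEnet <- function(X, y, spec, foldid) {
  best <- list(score = -Inf)
  yf <- as.numeric(y)
  for (a in spec$alphaGrid) {
    path <- tryCatch(
      glmnet::glmnet(X, yf, family = "binomial", alpha = a,
                     nlambda = spec$nLambda,
                     lambda.min.ratio = spec$lambdaMinRatio,
                     standardize = FALSE)$lambda,
      error = function(e) NULL)
    if (is.null(path)) next
    metric <- matrix(NA_real_, max(foldid), length(path))
    for (f in seq_len(max(foldid))) {
      tr <- foldid != f; te <- !tr
      if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) next
      fit <- tryCatch(
        glmnet::glmnet(X[tr, , drop = FALSE], yf[tr], family = "binomial",
                       alpha = a, lambda = path, standardize = FALSE),
        error = function(e) NULL)
      if (is.null(fit)) next
      pr <- predict(fit, X[te, , drop = FALSE], type = "response")
      nl <- ncol(pr)
      if (spec$tuneMetric == "auc") {
        metric[f, seq_len(nl)] <- vapply(seq_len(nl), function(j)
          rocAuc(pr[, j], y[te])$auc, numeric(1))
      } else {
        eps <- 1e-12
        metric[f, seq_len(nl)] <- vapply(seq_len(nl), function(j) {
          pj <- pmin(pmax(pr[, j], eps), 1 - eps)
          mean(-2 * (y[te] * log(pj) + (1 - y[te]) * log(1 - pj)))
        }, numeric(1))
      }
    }
    mm <- colMeans(metric, na.rm = TRUE)
    if (all(is.nan(mm))) next
    score <- if (spec$tuneMetric == "auc") mm else -mm
    # ties along the path (common under the AUC criterion on separable
    # data) resolve to the least-penalised lambda among the maxima, so
    # probabilities stay usable at the 0.5 threshold
    best.j <- which(score >= max(score, na.rm = TRUE) - 1e-12)
    j <- best.j[length(best.j)]
    if (is.finite(score[j]) && score[j] > best$score)
      best <- list(score = score[j], alpha = a, lambda = path[j], path = path)
  }
  if (!is.finite(best$score))
    stop("elastic-net tuning failed on every (alpha, lambda) pair")
  refit <- glmnet::glmnet(X, yf, family = "binomial", alpha = best$alpha,
                          lambda = best$path, standardize = FALSE)
  cf <- coef(refit, s = best$lambda)
  nz <- rownames(cf)[-1][abs(as.numeric(cf)[-1]) > 0]
  list(model = refit, alpha = best$alpha, lambda = best$lambda,
       selected = nz)
}

#' Fit a classifier on training data
#'
#' Elastic-net logistic regression is tuned over `alphaGrid` x a log-spaced
#' lambda path by mean inner-fold AUC (or deviance) and refit on the full
#' training data at the winning pair; a random forest uses fixed
#' hyperparameters with no inner tuning. Features are standardised to
#' training mean/SD when `standardize` is set, and the identical transform is
#' applied at prediction time. A tuned elastic net that retains zero
#' features is flagged `degenerate` and predicts the constant training
#' prevalence.
#'
#' @param x training expression matrix (genes x samples), already restricted
#'   to the candidate features.
#' @param labels binary training labels.
#' @param spec a [modelSpec].
#' @param innerFoldIds inner-fold ids for tuning (one per training sample);
#'   generated from `seed` when absent.
#' @param seed RNG seed (inner folds, forest).
#' @return a [FitResult-class].
#' @export
fitModel <- function(x, labels, spec = modelSpec(), innerFoldIds = NULL,
                     seed = 1) {
  m <- if (is(x, "NodeCohort")) exprs2(x) else as.matrix(x)
  pos <- asPositive(labels)
  stopifnot(!anyNA(pos), ncol(m) == length(pos))
  std <- standardizeTrain(m, spec$standardize)
  if (spec$family == "elastic_net_logistic") {
    if (is.null(innerFoldIds))
      innerFoldIds <- withSeed(deriveSeed(seed, "tunefolds"),
                               stratifiedFolds(pos, 5))
    tuned <- tuneEnet(t(std$x), pos, spec, innerFoldIds)
    degenerate <- length(tuned$selected) == 0
    fit <- new("FitResult", family = spec$family, features = rownames(m),
               selectedFeatures = tuned$selected, model = tuned$model,
               chosenAlpha = tuned$alpha, chosenLambda = tuned$lambda,
               center = std$center, scale = std$scale,
               degenerate = degenerate, prevalence = mean(pos),
               trainingAuc = NA_real_)
  } else {
    mtry <- if (is.null(spec$rfMtry)) max(1, floor(sqrt(nrow(m)))) else spec$rfMtry
    rf <- ranger::ranger(x = t(std$x), y = factor(pos, c(FALSE, TRUE)),
                         probability = TRUE, num.trees = spec$rfNumTrees,
                         mtry = mtry, seed = seed, num.threads = 1)
    fit <- new("FitResult", family = spec$family, features = rownames(m),
               selectedFeatures = rownames(m), model = rf,
               chosenAlpha = NA_real_, chosenLambda = NA_real_,
               center = std$center, scale = std$scale, degenerate = FALSE,
               prevalence = mean(pos), trainingAuc = NA_real_)
  }
  fit@trainingAuc <- if (fit@degenerate) 0.5 else
    rocAuc(predictFit(fit, m), pos)$auc
  fit
}

#' Predict class probabilities from a fitted model
#'
#' Applies the training-fold standardisation stored in the fit, then the
#' underlying model. Degenerate fits return the constant training prevalence.
#'
#' @param fit a [FitResult-class].
#' @param x expression matrix (genes x samples) containing the fit's
#'   features.
#' @return named numeric vector of `pN+` probabilities.
#' @export
predictFit <- function(fit, x) {
  m <- if (is(x, "NodeCohort")) exprs2(x) else as.matrix(x)
  missing <- setdiff(fit@features, rownames(m))
  if (length(missing))
    stop("matrix lacks ", length(missing), " model feature(s)")
  m <- m[fit@features, , drop = FALSE]
  if (fit@degenerate)
    return(setNames(rep(fit@prevalence, ncol(m)), colnames(m)))
  X <- t((m - fit@center[fit@features]) / fit@scale[fit@features])
  if (fit@family == "elastic_net_logistic") {
    pr <- predict(fit@model, X, s = fit@chosenLambda, type = "response")
    setNames(as.numeric(pr), colnames(m))
  } else {
    pr <- predict(fit@model, data = X, num.threads = 1)$predictions
    setNames(pr[, "TRUE"], colnames(m))
  }
}
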