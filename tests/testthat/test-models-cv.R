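test_that("AUC matches hand values and the brute-force concordance oracle", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))$auc, 0.75)
  expect_equal(rocAuc(c(5, 4, 1, 0), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(rocAuc(rep(2, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(rocAuc(1:4, rep(1, 4)), "both classes")
  set.seed(14)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    scores <- sample(round(rnorm(n), 1))  # rounding forces ties
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    expect_equal(rocAuc(scores, pos)$auc, bruteForceAuc(scores, pos))
  }
})

test_that("balanced accuracy averages sensitivity and specificity", {
  truth <- c(rep(TRUE, 4), rep(FALSE, 4))
  pred <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  expect_equal(balancedAccuracy(pred, truth), (1 + 0.5) / 2)
  expect_equal(balancedAccuracy(truth, truth), 1.0)
  expect_equal(balancedAccuracy(rep(FALSE, 8), truth), 0.5)
  expect_error(balancedAccuracy(pred, rep(TRUE, 8)), "both classes")
})

test_that("fold plans are stratified, sized to protocol, and reproducible", {
  lab <- rep(c("pN+", "pN0"), c(34, 66))
  names(lab) <- paste0("s", 1:100)
  plan <- makeFoldPlan(lab, kOuter = 5, kInner = 5, repeats = 10, seed = 2)
  expect_equal(dim(plan@outer), c(100L, 10L))
  # 10 repeats x 5 folds = the 50-outer-fold protocol
  expect_equal(plan@repeats * plan@kOuter, 50L)
  expect_equal(makeFoldPlan(lab, repeats = 5, seed = 2)@repeats * 5L, 25L)
  pos <- lab == "pN+"
  for (r in c(1, 10)) {
    counts <- table(plan@outer[pos, r])
    expect_true(all(counts %in% 6:7))
    # inner folds partition each outer training set
    for (f in 1:5) {
      inner <- plan@inner[[r]][[f]]
      expect_setequal(names(inner), names(lab)[plan@outer[, r] != f])
      expect_true(all(inner %in% 1:5))
    }
  }
  expect_identical(makeFoldPlan(lab, repeats = 2, seed = 7),
                   makeFoldPlan(lab, repeats = 2, seed = 7))
  expect_error(makeFoldPlan(rep(c("pN+", "pN0"), c(3, 60))), "kOuter")
})

test_that("feature selection recovers planted genes and demotes constants", {
  hits <- vapply(1:10, function(s) {
    cfg <- syntheticConfig(n_genes = 1000, n_samples_per_cohort = 200,
                           n_signal_genes = 50, effect_size_delta = 2,
                           seed = 400 + s)
    sim <- simulateCohortPair(cfg)
    sel <- selectFeatures(exprs2(sim$cohort1), nodeStatus(sim$cohort1),
                          method = "t_test", k = 100)
    sum(sim$truth$signal_genes_cohort1 %in% sel)
  }, numeric(1))
  expect_gte(median(hits), 40)

  set.seed(15)
  m <- rbind(matrix(rnorm(19 * 30), 19, 30), const = rep(3, 30))
  rownames(m) <- c(paste0("g", 1:19), "const")
  colnames(m) <- paste0("s", 1:30)
  lab <- rep(c("pN0", "pN+"), 15)
  for (meth in c("t_test", "wilcoxon")) {
    sel <- selectFeatures(m, lab, method = meth, k = 19)
    expect_false("const" %in% sel)
  }
  expect_error(selectFeatures(m, lab, method = "t_test", k = 21), "k exceeds")
})

test_that("selection on null data is unstable across seeds", {
  set.seed(16)
  m <- matrix(rnorm(800 * 60), 800, 60,
              dimnames = list(paste0("g", 1:800), paste0("s", 1:60)))
  sel <- lapply(1:2, function(s) {
    set.seed(1000 + s)
    lab <- sample(rep(c("pN0", "pN+"), 30))
    selectFeatures(m, lab, method = "t_test", k = 40)
  })
  jac <- length(intersect(sel[[1]], sel[[2]])) /
    length(union(sel[[1]], sel[[2]]))
  expect_lt(jac, 0.3)  # expectation ~ k/n_genes = 0.05
})

test_that("elastic net honours penalty structure and degenerate contracts", {
  set.seed(17)
  # two perfectly separable clusters
  m <- cbind(matrix(rnorm(20 * 30, -2), 20, 30),
             matrix(rnorm(20 * 30, 2), 20, 30))
  dimnames(m) <- list(paste0("g", 1:20), paste0("s", 1:60))
  lab <- rep(c("pN0", "pN+"), each = 30)
  fit <- fitModel(m, lab, seed = 1)
  expect_equal(fit@trainingAuc, 1.0)

  # ridge (alpha = 0) keeps every feature
  ridge <- fitModel(m, lab, spec = modelSpec(alphaGrid = 0), seed = 1)
  expect_setequal(ridge@selectedFeatures, rownames(m))

  # pure noise under lasso + deviance tuning: the null model wins at times,
  # and every such degenerate fit must honour its contract (flag set,
  # constant-prevalence prediction, AUC pinned at 0.5)
  n.degen <- 0
  for (s in 1:10) {
    set.seed(200 + s)
    mn <- matrix(rnorm(20 * 200), 20, 200,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:200)))
    labn <- sample(rep(c("pN0", "pN+"), 100))
    f <- fitModel(mn, labn,
                  spec = modelSpec(alphaGrid = 1, tuneMetric = "deviance"),
                  seed = s)
    if (f@degenerate) {
      n.degen <- n.degen + 1
      expect_true(all(predictFit(f, mn) == f@prevalence))
      expect_equal(f@trainingAuc, 0.5)
      expect_length(f@selectedFeatures, 0)
    }
  }
  expect_gte(n.degen, 1)
})

test_that("nested evaluation is deterministic and destroyed by permutation", {
  cfg <- syntheticConfig(n_genes = 300, n_samples_per_cohort = 120,
                         n_signal_genes = 30, effect_size_delta = 1.5,
                         seed = 23)
  sim <- simulateCohortPair(cfg)
  x <- sim$cohort1
  sig <- sim$truth$signal_genes_cohort1
  plan <- makeFoldPlan(nodeStatus(x), seed = 3, sampleIds = colnames(x))
  r1 <- nestedCvEvaluate(x, plan = plan, signature = sig, seed = 5)
  r2 <- nestedCvEvaluate(x, plan = plan, signature = sig, seed = 5)
  expect_identical(r1@perFold, r2@perFold)
  expect_gt(r1@meanAuc, 0.75)  # planted truth genes carry signal

  # permuting the labels kills it
  set.seed(31)
  perm.lab <- sample(as.character(nodeStatus(x)))
  plan.p <- makeFoldPlan(perm.lab, seed = 3, sampleIds = colnames(x))
  rp <- nestedCvEvaluate(exprs2(x), labels = perm.lab, plan = plan.p,
                         signature = sig, seed = 5)
  expect_lt(abs(rp@meanAuc - 0.5), 0.2)

  # evaluations under one plan share the exact same partitions
  r3 <- nestedCvEvaluate(x, plan = plan, signature = sig[1:10], seed = 9)
  expect_identical(r1@perFold[c("repeat_id", "outer_fold")],
                   r3@perFold[c("repeat_id", "outer_fold")])
})

test_that("leaky selection inflates null AUC; nested stays unbiased", {
  seeds <- 1:8
  res <- t(vapply(seeds, function(s) {
    cfg <- syntheticConfig(n_genes = 1000, n_samples_per_cohort = 100,
                           effect_size_delta = 0, subtype_shift_sd = 0,
                           cohort_shift_sd = 0, seed = 600 + s)
    x <- simulateCohortPair(cfg)$cohort1
    plan <- makeFoldPlan(nodeStatus(x), seed = s, sampleIds = colnames(x))
    spec <- modelSpec(alphaGrid = c(0, 0.5, 1))  # leakage is grid-agnostic
    nested <- nestedCvEvaluate(x, spec = spec, plan = plan,
                               fsMethod = "t_test", k = 50, seed = s)
    leaky <- leakyEvaluate(x, spec = spec, plan = plan, fsMethod = "t_test",
                           k = 50, seed = s)
    c(nested = nested@meanAuc, leaky = leaky@meanAuc)
  }, numeric(2)))
  # nested null estimates centred on 0.5
  expect_gt(t.test(res[, "nested"], mu = 0.5)$p.value, 0.01)
  # leaky stochastically larger (paired one-sided Wilcoxon)
  expect_lt(wilcox.test(res[, "leaky"], res[, "nested"], paired = TRUE,
                        alternative = "greater")$p.value, 0.01)
})

test_that("final models reapply exactly on their own training cohort", {
  cfg <- syntheticConfig(n_genes = 400, n_samples_per_cohort = 150,
                         n_signal_genes = 30, effect_size_delta = 1.5,
                         shared_fraction_rho = 1, seed = 41)
  sim <- simulateCohortPair(cfg)
  suppressMessages(
    fin <- trainFinalAndApply(sim$cohort1, sim$cohort2, fsMethod = "t_test",
                              k = 50, seed = 13))
  x1 <- sim$cohort1
  pr <- predictFit(fin$fit, exprs2(x1)[fin$genesUsed, ])
  expect_equal(rocAuc(pr, nodeStatus(x1))$auc, fin$trainingAuc,
               tolerance = 1e-12)
  # shared planted signal transfers
  expect_gt(fin$externalAuc, 0.7)
})

test_that("CV results record the feature-selection audit trail", {
  cfg <- syntheticConfig(n_genes = 200, n_samples_per_cohort = 80,
                         n_signal_genes = 20, effect_size_delta = 1.5,
                         seed = 51)
  x <- simulateCohortPair(cfg)$cohort1
  plan <- makeFoldPlan(nodeStatus(x), seed = 3, sampleIds = colnames(x))
  res <- nestedCvEvaluate(x, plan = plan, fsMethod = "t_test", k = 25,
                          seed = 7)
  expect_false(res@leaky)
  expect_equal(nrow(res@perFold), 5L)
  expect_true(all(vapply(res@perFold$selected_features, length,
                         integer(1)) <= 25))
  leaky <- leakyEvaluate(x, plan = plan, fsMethod = "t_test", k = 25,
                         seed = 7)
  expect_true(leaky@leaky)
  # the leaky arm draws every fold's model from one global candidate pool
  sel <- leaky@perFold$selected_features
  expect_lte(length(unique(unlist(sel))), 25L)
})
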