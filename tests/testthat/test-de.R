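test_that("zero filter and median centering follow their boundary rules", {
  m <- rbind(g1 = c(rep(0, 6), rep(1, 4)),   # 0.6 > 0.5 -> removed
             g2 = c(rep(0, 5), rep(1, 5)),   # exactly 0.5 -> kept
             g3 = rep(2, 10))
  x <- toyCohort(m)
  expect_message(xf <- filterLowExpression(x), "removed 1")
  expect_equal(rownames(xf), c("g2", "g3"))
  expect_error(filterLowExpression(medianCenter(x)), "precede")

  xc <- medianCenter(toyCohort(rbind(c(1, 2, 3), c(5, 5, 5)),
                               genes = c("a", "b")))
  expect_equal(unname(exprs2(xc)["a", ]), c(-1, 0, 1))
  expect_equal(unname(exprs2(xc)["b", ]), c(0, 0, 0))
  expect_true(isCentered(xc))
  expect_equal(exprs2(medianCenter(xc)), exprs2(xc))  # idempotent
})

test_that("moderated t with d0 = 0 equals the ordinary pooled t exactly", {
  set.seed(11)
  m <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  lab <- rep(c("pN0", "pN+"), each = 6)
  x <- toyCohort(m, genes = rownames(m), nodeStatus = lab)
  de <- differentialExpression(x, priorDf = 0)
  for (g in c(1, 17, 50)) {
    tt <- t.test(m[g, lab == "pN+"], m[g, lab == "pN0"], var.equal = TRUE)
    expect_equal(de$t_mod[g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(de$p[g], tt$p.value, tolerance = 1e-10)
  }
  expect_error(differentialExpression(x, labels = rep("pN+", 12)), ">= 2")
})

test_that("moderated-t statistics agree with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(4)
  m <- matrix(rnorm(300 * 20), 300, 20,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:20)))
  m[1:20, 11:20] <- m[1:20, 11:20] + 1
  lab <- rep(c("pN0", "pN+"), each = 10)
  de <- differentialExpression(toyCohort(m, genes = rownames(m),
                                         nodeStatus = lab))
  design <- cbind(1, lab == "pN+")
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(de, "prior")$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(de$t_mod, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
  expect_equal(de$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
})

test_that("moderated t is invariant to sample order and per-gene shifts", {
  set.seed(12)
  m <- matrix(rnorm(40 * 16), 40, 16,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:16)))
  lab <- factor(rep(c("pN0", "pN+"), 8), levels = c("pN0", "pN+"))
  de <- differentialExpression(m, labels = lab)
  perm <- sample(16)
  de.p <- differentialExpression(m[, perm], labels = lab[perm])
  expect_equal(de, de.p)
  m2 <- m + rnorm(40)  # constant added per gene (recycled down columns)
  de.s <- differentialExpression(m2, labels = lab)
  expect_equal(de.s$log2fc, de$log2fc, tolerance = 1e-12)
  expect_equal(de.s$t_mod, de$t_mod, tolerance = 1e-9)
})

test_that("BH adjustment matches hand values and the exhaustive oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(rep(0.05, 10)), rep(0.05, 10))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(1:12, 1))
    expect_equal(bhAdjust(p), bruteForceBH(p))
  }
})

test_that("top lists respect the ceil rule, sign partition, and k", {
  set.seed(5)
  n <- 16297
  de <- data.frame(gene = sprintf("g%05d", 1:n),
                   log2fc = rnorm(n), t_mod = rnorm(n),
                   stringsAsFactors = FALSE)
  de$rank_metric <- de$t_mod
  up10 <- suppressMessages(topGeneLists(de, "up", fraction = 0.1))
  expect_length(up10, 1630)

  up25 <- suppressMessages(topGeneLists(de, "up", k = 25))
  dn25 <- suppressMessages(topGeneLists(de, "down", k = 25))
  expect_length(up25, 25)
  expect_length(dn25, 25)
  expect_length(intersect(up25, dn25), 0)

  up.all <- suppressMessages(topGeneLists(de, "up", fraction = 1))
  dn.all <- suppressMessages(topGeneLists(de, "down", fraction = 1))
  expect_equal(sort(c(up.all, dn.all)), sort(de$gene))  # exact partition
  expect_true(all(de$t_mod[match(up.all, de$gene)] > 0))

  expect_error(topGeneLists(de, "up", k = n + 1), "exceeds")
  expect_error(topGeneLists(de, "up"), "exactly one")
})

test_that("two-list overlap reproduces the printed chance expectations", {
  u <- sprintf("g%05d", 1:16297)
  ov10 <- listOverlapTest(u[1:1630], u[101:1730], 16297)
  expect_equal(round(ov10@expected), 163)
  ov5 <- listOverlapTest(u[1:815], u[201:1015], 16297)
  expect_equal(round(ov5@expected), 41)
  ov1 <- listOverlapTest(u[1:163], u[1:163], 16297)
  expect_equal(round(ov1@expected, 1), 1.6)
  expect_equal(ov1@observed, 163)
  expect_lt(ov1@pValue, 1e-100)

  # expected equals the hypergeometric mean exactly
  nA <- 40; nB <- 25; N <- 500
  hyper.mean <- sum(0:nA * dhyper(0:nA, nA, N - nA, nB))
  ov <- listOverlapTest(paste0("x", 1:nA), paste0("y", 1:nB), N)
  expect_equal(ov@expected, hyper.mean, tolerance = 1e-12)

  # simulated random-list overlap matches within Monte-Carlo error
  set.seed(9)
  sims <- replicate(400, length(intersect(sample(u[1:500], 60),
                                          sample(u[1:500], 80))))
  exp.sim <- listOverlapTest(u[1:60], u[1:80], 500)@expected
  expect_lt(abs(mean(sims) - exp.sim), 3 * sd(sims) / sqrt(400))

  expect_error(listOverlapTest(u[1:100], u, 200), "universe")
})
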