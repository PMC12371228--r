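test_that("signature matching partitions genes and enforces representability", {
  x <- toyCohort(matrix(0, 3, 2), genes = c("A", "C", "D"))
  sig <- GeneSignature("s", c("A", "B", "C"))
  suppressMessages(ms <- matchSignature(sig, x))
  expect_equal(matchedGenes(ms), c("A", "C"))
  expect_equal(unmatchedGenes(ms), "B")

  full <- GeneSignature("f", c("A", "D"))
  suppressMessages(msf <- matchSignature(full, x))
  expect_length(unmatchedGenes(msf), 0)

  expect_error(suppressMessages(
    matchSignature(GeneSignature("none", c("X", "Y")), x)),
    "not representable")
})

test_that("directionality inference follows the strict-above-median rule", {
  # g1: +1 in every pN+ sample, median 0 -> up
  # g2: pN+ mean exactly at the dataset median -> down (tie rule)
  # g3: reported down stays down even though its pN+ mean is above median
  m <- rbind(g1 = c(1, 1, -1, -1, 0, 0),
             g2 = c(2, 0, 1, 1, 1, 1),
             g3 = c(5, 5, 0, 0, 0, 0))
  x <- toyCohort(m, samples = paste0("s", 1:6),
                 nodeStatus = c("pN+", "pN+", "pN0", "pN0", "pN0", "pN0"))
  sig <- GeneSignature("s", c("g1", "g2", "g3"),
                       direction = c(g3 = "down"))
  suppressMessages(ms <- matchSignature(sig, x))
  ms <- inferDirectionality(ms, x)
  dir <- resolvedDirection(ms)
  expect_equal(unname(dir["g1"]), "up")
  expect_equal(unname(dir["g2"]), "down")  # mean(pN+) = 1 = median -> down
  expect_equal(unname(dir["g3"]), "down")
  expect_equal(unname(directionProvenance(ms)[c("g1", "g3")]),
               c("inferred", "reported"))
  # no positive samples -> error
  x0 <- toyCohort(m, nodeStatus = rep("pN0", 6))
  expect_error(inferDirectionality(ms, x0), "no pN\\+")
})

test_that("mean signature score computes up-minus-down on centered data", {
  m <- rbind(g1 = c(1, 0), g2 = c(0, 0), g3 = c(-1, 0))
  x <- toyCohort(m, centered = TRUE)
  sig <- GeneSignature("s", c("g1", "g2", "g3"),
                       direction = c(g1 = "up", g2 = "up", g3 = "down"))
  suppressMessages(ms <- matchSignature(sig, x))
  sc <- meanSignatureScore(ms, x)
  expect_equal(unname(sc), c(0.5 - (-1), 0))  # 1.5 and all-zero sample -> 0

  # only-up and only-down conventions
  up <- GeneSignature("u", c("g1", "g2"),
                      direction = c(g1 = "up", g2 = "up"))
  dn <- GeneSignature("d", c("g1", "g3"),
                      direction = c(g1 = "down", g3 = "down"))
  suppressMessages({
    expect_equal(unname(meanSignatureScore(matchSignature(up, x), x)[1]), 0.5)
    expect_equal(unname(meanSignatureScore(matchSignature(dn, x), x)[1]), 0)
  })

  # uncentered input refused
  xu <- toyCohort(m, centered = FALSE)
  expect_error(meanSignatureScore(ms, xu), "center")
})

test_that("scores are order-invariant and direction-antisymmetric", {
  set.seed(3)
  m <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  x <- toyCohort(m, genes = rownames(m), samples = colnames(m),
                 centered = TRUE)
  sig <- GeneSignature("s", rownames(m),
                       direction = setNames(rep(c("up", "down"), 3),
                                            rownames(m)))
  suppressMessages(ms <- matchSignature(sig, x))
  sc <- meanSignatureScore(ms, x)
  # sample order
  perm <- sample(10)
  sc.p <- meanSignatureScore(ms, x[, perm])
  expect_equal(sc.p, sc[perm])
  # gene order within the signature
  gperm <- sample(6)
  sig2 <- GeneSignature("s2", rownames(m)[gperm],
                        direction = signatureDirection(sig)[gperm])
  suppressMessages(ms2 <- matchSignature(sig2, x))
  expect_equal(unname(meanSignatureScore(ms2, x)), unname(sc))
  # flipping every direction negates every score
  flip <- ifelse(signatureDirection(sig) == "up", "down", "up")
  sigf <- GeneSignature("sf", rownames(m), direction = flip)
  suppressMessages(msf <- matchSignature(sigf, x))
  expect_equal(meanSignatureScore(msf, x), -sc)
})

test_that("random signatures score at chance, inferred directions above it", {
  aucs <- matrix(NA_real_, 20, 2)
  for (s in 1:20) {
    cfg <- syntheticConfig(n_genes = 500, n_samples_per_cohort = 150,
                           effect_size_delta = 0, seed = 1000 + s)
    x <- medianCenter(simulateCohortPair(cfg)$cohort1)
    set.seed(s)
    genes <- sample(rownames(x), 200)
    sig <- GeneSignature("r", genes,
                         direction = setNames(rep(c("up", "down"), 100),
                                              genes))
    suppressMessages(ms <- matchSignature(sig, x))
    aucs[s, 1] <- rocAuc(meanSignatureScore(ms, x), nodeStatus(x))$auc
    # same signature, directions inferred from the very data being scored
    sigu <- GeneSignature("ru", genes)
    suppressMessages(msu <- matchSignature(sigu, x))
    msu <- inferDirectionality(msu, x)
    aucs[s, 2] <- rocAuc(meanSignatureScore(msu, x), nodeStatus(x))$auc
  }
  expect_lt(abs(mean(aucs[, 1]) - 0.5), 0.05)   # fixed directions: chance
  expect_gt(mean(aucs[, 2]), 0.5)               # inferred: one-sided optimism
  expect_gt(mean(aucs[, 2]), mean(aucs[, 1]))
})

test_that("signature overlap null matches the analytic expectation", {
  # identical signatures overlap completely
  g <- paste0("g", 1:10)
  ov <- signatureOverlap(list(GeneSignature("a", g), GeneSignature("b", g)),
                         universeSize = 1000, nSims = 200, seed = 1)
  expect_equal(ov@observed, 10)
  expect_lt(ov@pValue, 0.05)

  # two 100-gene signatures in a 10000-gene universe: E = 1.0
  ov2 <- signatureOverlap(sizes = c(100, 100), universeSize = 10000,
                          nSims = 4000, seed = 2)
  expect_equal(ov2@analytic, 1.0)
  expect_lt(abs(ov2@expected - 1.0), 2 * sqrt(1.0) / sqrt(4000) * 3)

  expect_error(signatureOverlap(sizes = c(10, 10), universeSize = 100,
                                nSims = 50), "nSims")
  expect_error(signatureOverlap(sizes = c(10, 200), universeSize = 100,
                                nSims = 200), "universeSize")
})
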