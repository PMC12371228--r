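#' Remove genes with excess zeros
#'
#' Drops genes whose fraction of exactly-zero values exceeds
#' `maxZeroFraction` (strictly greater; a gene with zeros in exactly half the
#' samples is kept). The filter is defined on uncentered values and must
#' precede median centering.
#'
#' @param x an uncentered [NodeCohort].
#' @param maxZeroFraction threshold (default 0.5).
#' @return the filtered [NodeCohort]; the removal count is reported.
#' @export
filterLowExpression <- function(x, maxZeroFraction = 0.5) {
  if (isCentered(x))
    stop("filter must precede centering: input is already median-centered")
  zf <- rowMeans(exprs2(x) == 0)
  drop <- zf > maxZeroFraction
  message("removed ", sum(drop), " gene(s) with zero-fraction > ",
          maxZeroFraction, " (", nrow(x) - sum(drop), " remain)")
  x[!drop, ]
}

#' Median-center each gene across samples
#'
#' After centering, every gene's median over samples is 0 (to numeric
#' tolerance) and the `centered` flag is set. Idempotent.
#'
#' @param x a [NodeCohort].
#' @return the centered [NodeCohort].
#' @export
medianCenter <- function(x) {
  m <- exprs2(x)
  med <- apply(m, 1, median)
  SummarizedExperiment::assay(x, "exprs") <- m - med
  S4Vectors::metadata(x)$centered <- TRUE
  x
}

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf)),
# used by the moment-matching prior fit.
trigammaInverse <- function(x) {
  out <- x
  small <- x < 1e-6
  large <- x > 1e7
  out[small] <- 1 / x[small]
  out[large] <- 1 / sqrt(x[large])
  mid <- !small & !large
  if (any(mid)) {
    y <- 0.5 + 1 / x[mid]
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / x[mid]) / psigamma(y, deriv = 2)
      y <- y + dif
      if (max(-dif / y) < 1e-8) break
    }
    out[mid] <- y
  }
  out
}

# Empirical-Bayes prior (d0, s0^2) for gene-wise variances: moment matching
# on log s^2 under the scaled-F model s^2 ~ s0^2 F(d, d0). Underdispersed
# log s^2 (moment estimate of d0 non-finite) falls back to d0 = Inf, i.e.
# fully pooled variance.
estimateVariancePrior <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  if (sum(ok) < 2) return(list(d0 = Inf, s02 = mean(s2[is.finite(s2)])))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigammaInverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- mean(s2[is.finite(s2)])  # fully pooled variance
  }
  list(d0 = d0, s02 = s02)
}

#' Two-group moderated-t differential expression
#'
#' Gene-wise comparison of `pN+` versus `pN0` samples: ordinary two-group
#' fit per gene (log2 fold change = mean(pN+) - mean(pN0), pooled residual
#' variance `s^2` on `d = n - 2` df), then empirical-Bayes moderation — the
#' prior `(d0, s0^2)` is estimated by moment matching on the `log s^2`
#' distribution, the posterior variance is
#' `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)`, and the moderated statistic is
#' `t = log2fc / (s~ sqrt(1/n+ + 1/n0))` on `d0 + d` df, with two-sided
#' p-values and Benjamini-Hochberg q-values.
#'
#' @param x a [NodeCohort] (centered or not; the statistic is location
#'   invariant).
#' @param labels optional labels (defaults to `nodeStatus(x)`); samples with
#'   `NA` labels are dropped.
#' @param priorDf override of the prior df `d0`: `NULL` (default) estimates
#'   it from the data, `0` gives the ordinary pooled-variance t-test, `Inf`
#'   fully pools the variance.
#' @return data.frame (one row per gene) with columns `gene`, `log2fc`,
#'   `t_mod`, `p`, `q`, `rank_metric` (= `t_mod`); attributes `prior`
#'   (`d0`, `s02`) and `n` (class sizes).
#' @export
differentialExpression <- function(x, labels = NULL, priorDf = NULL) {
  m <- if (is(x, "NodeCohort")) exprs2(x) else as.matrix(x)
  if (is.null(labels) && is(x, "NodeCohort")) labels <- nodeStatus(x)
  if (is.null(labels)) stop("labels required")
  pos <- asPositive(labels)
  keep <- !is.na(pos)
  m <- m[, keep, drop = FALSE]
  pos <- pos[keep]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 < 2 || n0 < 2) stop("each class needs >= 2 samples (pN+ = ", n1,
                             ", pN0 = ", n0, ")")
  m1 <- rowMeans(m[, pos, drop = FALSE])
  m0 <- rowMeans(m[, !pos, drop = FALSE])
  lfc <- m1 - m0
  ss <- rowSums((m[, pos, drop = FALSE] - m1)^2) +
    rowSums((m[, !pos, drop = FALSE] - m0)^2)
  d <- n1 + n0 - 2
  s2 <- ss / d
  prior <- if (is.null(priorDf)) estimateVariancePrior(s2, d)
           else list(d0 = priorDf, s02 = if (is.finite(priorDf) && priorDf > 0)
             estimateVariancePrior(s2, d)$s02 else mean(s2))
  d0 <- prior$d0
  s2post <- if (is.infinite(d0)) rep(prior$s02, length(s2))
            else if (d0 == 0) s2
            else (d0 * prior$s02 + d * s2) / (d0 + d)
  se <- sqrt(s2post * (1 / n1 + 1 / n0))
  t <- lfc / se
  t[se == 0 & lfc == 0] <- 0
  # total df capped at the pooled residual df, so an infinite prior yields
  # the fully pooled (large but finite) reference distribution
  df.total <- min(d0 + d, d * length(s2))
  p <- 2 * pt(-abs(t), df = df.total)
  p[is.na(p) & is.infinite(t)] <- 0
  out <- data.frame(gene = rownames(m), log2fc = lfc, t_mod = t, p = p,
                    q = bhAdjust(p), rank_metric = t,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "prior") <- list(d0 = d0, s02 = prior$s02)
  attr(out, "n") <- c(pN_pos = n1, pN0 = n0)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) m / j`, mapped back to
#' input order and capped at 1.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of q-values in input order.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Top up-/down-regulated gene lists
#'
#' Genes ranked by the signed statistic (`t_mod` by default, `log2fc` via
#' `metric`), descending for `up` lists and ascending for `down`, truncated
#' to `ceil(fraction * m)` genes (with `m` the number of tested genes) or to
#' `k`. The sign partitions the universe: genes with statistic exactly 0
#' belong to the `down` side, so a 100% up list plus a 100% down list covers
#' every gene exactly once. Ties in the ranking metric are broken by larger
#' `|log2fc|`, then lexicographic gene symbol; any tie-break is reported.
#'
#' @param de data.frame from [differentialExpression].
#' @param direction `"up"` or `"down"`.
#' @param fraction fraction of the tested genes (exclusive with `k`).
#' @param k absolute list size (exclusive with `fraction`).
#' @param metric ranking metric: `"t_mod"` (default) or `"log2fc"`.
#' @return character vector of gene symbols.
#' @export
topGeneLists <- function(de, direction = c("up", "down"), fraction = NULL,
                         k = NULL, metric = c("t_mod", "log2fc")) {
  direction <- match.arg(direction)
  metric <- match.arg(metric)
  if (is.null(fraction) == is.null(k))
    stop("give exactly one of fraction or k")
  m <- nrow(de)
  size <- if (!is.null(fraction)) ceiling(fraction * m) else as.integer(k)
  if (size > m) stop("requested list size ", size, " exceeds ", m, " genes")
  stat <- de[[metric]]
  eligible <- if (direction == "up") stat > 0 else stat <= 0
  sub <- de[eligible, , drop = FALSE]
  s <- sub[[metric]]
  ord <- order(if (direction == "up") -s else s, -abs(sub$log2fc), sub$gene)
  if (anyDuplicated(s[ord][seq_len(min(size, length(ord)))]))
    message("tie-break applied within the ", direction, " ranking")
  n.take <- min(size, nrow(sub))
  if (n.take < size && !is.null(k))
    warning("only ", n.take, " genes on the ", direction, " side; returning ",
            n.take)
  sub$gene[ord][seq_len(n.take)]
}

#' Two-list overlap against the hypergeometric expectation
#'
#' Observed overlap `|A intersect B|`, expected-by-chance overlap
#' `|A| |B| / N` (the hypergeometric mean for random lists of the same sizes
#' from a universe of `N` genes), and a Fisher's exact p-value on the 2x2
#' membership table (one-sided, enrichment).
#'
#' @param listA,listB character vectors of genes (subsets of the universe).
#' @param universeSize universe size `N`.
#' @return an [OverlapResult-class] with `method = "hypergeometric"`.
#' @export
listOverlapTest <- function(listA, listB, universeSize) {
  listA <- unique(listA); listB <- unique(listB)
  nA <- length(listA); nB <- length(listB)
  if (universeSize < max(nA, nB))
    stop("universe smaller than one of the lists")
  obs <- length(intersect(listA, listB))
  expected <- nA * nB / universeSize
  tab <- matrix(c(obs, nA - obs, nB - obs, universeSize - nA - nB + obs), 2)
  p <- fisher.test(tab, alternative = "greater")$p.value
  new("OverlapResult", observed = as.numeric(obs), expected = expected,
      analytic = expected, pValue = p, listSizes = c(nA, nB),
      universeSize = as.integer(universeSize), method = "hypergeometric",
      nSims = 0L)
}
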