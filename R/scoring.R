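#' Match a signature against a dataset
#'
#' Partitions signature genes into those present in the expression matrix
#' (matched, case-sensitive symbol comparison after trimming) and those
#' absent. Genes whose original report gives a direction keep it, with
#' provenance `reported`; genes of unknown direction stay unresolved until
#' [inferDirectionality] is applied.
#'
#' @param sig a [GeneSignature-class].
#' @param x a [NodeCohort] (or matrix with gene rownames).
#' @return a [MatchedSignature-class]; the match rate is reported in a
#'   message.
#' @export
matchSignature <- function(sig, x) {
  universe <- if (is(x, "NodeCohort")) rownames(x) else rownames(as.matrix(x))
  present <- sig@genes %in% universe
  if (!any(present))
    stop("signature ", sQuote(sig@name), " not representable in dataset: ",
         "zero matched genes")
  matched <- sig@genes[present]
  unmatched <- sig@genes[!present]
  dir <- sig@direction[matched]
  resolved <- ifelse(dir %in% c("up", "down"), dir, NA_character_)
  prov <- ifelse(dir %in% c("up", "down"), "reported", NA_character_)
  message("signature ", sQuote(sig@name), ": matched ", length(matched),
          "/", length(sig@genes), " genes")
  new("MatchedSignature", signature = sig, matchedGenes = matched,
      unmatchedGenes = unmatched,
      resolvedDirection = setNames(resolved, matched),
      provenance = setNames(prov, matched))
}

#' Infer missing gene directionality from the data
#'
#' For each matched gene whose original report gives no direction, the gene
#' is set to `up` (in `pN+`) when its expression in node-positive samples is
#' strictly above its median expression over all samples of the dataset, and
#' to `down` otherwise (ties go to `down`). Genes with a reported direction
#' are never modified. The central tendency of the node-positive side is the
#' mean by default (matching the mean-score construction); `statistic =
#' "median"` switches to the median.
#'
#' Note the built-in optimism: when the same dataset is later scored, the
#' inferred directions are tuned to it, biasing score AUCs upward — the very
#' effect this package is designed to expose.
#'
#' @param ms a [MatchedSignature-class].
#' @param x the [NodeCohort] used for inference.
#' @param labels optional labels (defaults to `nodeStatus(x)`).
#' @param statistic summary of pN+ expression: `"mean"` (default) or
#'   `"median"`.
#' @return the [MatchedSignature-class] with all directions resolved;
#'   inferred genes carry provenance `inferred`.
#' @export
inferDirectionality <- function(ms, x, labels = NULL,
                                statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  m <- if (is(x, "NodeCohort")) exprs2(x) else as.matrix(x)
  if (is.null(labels)) labels <- nodeStatus(x)
  if (is.null(labels)) stop("labels required (cohort carries none)")
  pos <- asPositive(labels)
  keep <- !is.na(pos)
  m <- m[, keep, drop = FALSE]
  pos <- pos[keep]
  if (!any(pos)) stop("no pN+ samples: cannot infer directionality")
  todo <- ms@matchedGenes[is.na(ms@resolvedDirection[ms@matchedGenes])]
  if (length(todo)) {
    sub <- m[todo, , drop = FALSE]
    posStat <- if (statistic == "mean") rowMeans(sub[, pos, drop = FALSE])
               else apply(sub[, pos, drop = FALSE], 1, median)
    allMedian <- apply(sub, 1, median)
    dir <- ifelse(posStat > allMedian, "up", "down")  # tie -> down
    ms@resolvedDirection[todo] <- dir
    ms@provenance[todo] <- "inferred"
  }
  validObject(ms)
  ms
}

#' Mean signature score
#'
#' Per-sample score on median-centered log2 data: the mean expression of the
#' signature's up genes minus the mean expression of its down genes. A
#' signature with only up genes scores `mean(up)`; only down genes,
#' `-mean(down)`.
#'
#' @param ms a fully direction-resolved [MatchedSignature-class].
#' @param x a median-centered [NodeCohort] (the `centered` flag is enforced).
#' @return named numeric vector of per-sample scores.
#' @export
meanSignatureScore <- function(ms, x) {
  if (is(x, "NodeCohort")) {
    if (!isCentered(x))
      stop("matrix is not median-centered; run medianCenter() first")
    m <- exprs2(x)
  } else m <- as.matrix(x)
  dir <- ms@resolvedDirection
  if (anyNA(dir))
    stop("unresolved gene direction(s); run inferDirectionality() first")
  up <- names(dir)[dir == "up"]
  down <- names(dir)[dir == "down"]
  score <- rep(0, ncol(m))
  if (length(up)) score <- score + colMeans(m[up, , drop = FALSE])
  if (length(down)) score <- score - colMeans(m[down, , drop = FALSE])
  setNames(score, colnames(m))
}

#' Multi-signature gene overlap against a redraw null
#'
#' Observed statistic: the number of distinct genes appearing in at least two
#' of the signatures. The null redraws each signature uniformly without
#' replacement from a gene universe of the given size, independently across
#' signatures, and averages the statistic over `nSims` replicates. The
#' analytic first-order expectation \eqn{\sum_{i<j} n_i n_j / N} is reported
#' alongside as a cross-check. The p-value is the simulated tail probability
#' of an overlap at least as large as observed.
#'
#' @param signatures list of [GeneSignature-class] (or character vectors of
#'   genes). May be `NULL` when only `sizes` is given (expected value only;
#'   observed and p are `NA`).
#' @param universeSize number of genes in the universe.
#' @param nSims simulation replicates (>= 100; default 10000).
#' @param seed RNG seed for the null.
#' @param sizes optional integer vector of signature sizes overriding
#'   `signatures` for the null (e.g. published matched-gene counts).
#' @return an [OverlapResult-class] with `method = "simulation"`.
#' @export
signatureOverlap <- function(signatures = NULL, universeSize, nSims = 10000,
                             seed = 1, sizes = NULL) {
  if (nSims < 100) stop("nSims < 100 gives an unstable null; use >= 100")
  observed <- NA_real_
  if (!is.null(signatures)) {
    gene.lists <- lapply(signatures, function(s)
      if (is(s, "GeneSignature")) s@genes else as.character(s))
    if (is.null(sizes)) sizes <- lengths(gene.lists)
    all.g <- unlist(gene.lists)
    observed <- length(unique(all.g[duplicated(all.g)]))
  }
  if (is.null(sizes)) stop("either signatures or sizes must be supplied")
  sizes <- as.integer(sizes)
  if (length(sizes) < 2) stop("need at least two signatures")
  if (universeSize < max(sizes))
    stop("universeSize must be at least the largest signature")
  sims <- withSeed(seed, {
    vapply(seq_len(nSims), function(i) {
      draws <- unlist(lapply(sizes, function(n) sample.int(universeSize, n)))
      length(unique(draws[duplicated(draws)]))
    }, numeric(1))
  })
  analytic <- sum(outer(sizes, sizes)[lower.tri(diag(length(sizes)))]) /
    universeSize
  p <- if (is.na(observed)) NA_real_ else
    (1 + sum(sims >= observed)) / (nSims + 1)
  new("OverlapResult", observed = observed, expected = mean(sims),
      analytic = analytic, pValue = p, listSizes = sizes,
      universeSize = as.integer(universeSize), method = "simulation",
      nSims = as.integer(nSims))
}
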