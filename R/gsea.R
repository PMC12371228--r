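# Weighted KS running-sum enrichment score on a descending-sorted statistic
# vector. Hits increment by |stat|^weight / sum(|stat|^weight over hits),
# misses decrement by 1 / (N - n_hits); ES is the signed maximum deviation.
gseaEnrichmentScore <- function(statsSorted, hitIdx, weight = 1) {
  N <- length(statsSorted)
  nh <- length(hitIdx)
  if (nh == 0L || nh >= N) stop("hit set must be a proper non-empty subset")
  w <- abs(statsSorted[hitIdx])^weight
  if (sum(w) == 0) w <- rep(1, nh)  # all hit stats zero: fall back to equal
  step <- rep(-1 / (N - nh), N)
  step[hitIdx] <- w / sum(w)
  run <- cumsum(step)
  run[which.max(abs(run))]
}

#' Pre-ranked gene set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov enrichment on a ranked gene list:
#' genes are sorted by the supplied statistic (descending); for each set the
#' enrichment score (ES) is the signed maximum deviation of a running sum
#' whose hit increments are `|stat|^weight` (normalised) and whose miss
#' decrements are `1/(N - n_hits)`. The null redraws each set's positions
#' uniformly among the ranked genes (`nPerm` gene-label permutations). NES is
#' ES divided by the mean |null ES| of matching sign; the permutation p-value
#' is the same-sign tail probability; FDR q follows the positive/negative
#' normalised-null ratio convention (each tail handled separately).
#'
#' @param stats named numeric vector: gene -> ranking statistic (finite).
#' @param sets list of [GeneSignature-class] or character vectors.
#' @param weight exponent on `|stat|` for hit increments (default 1;
#'   0 gives the unweighted KS statistic).
#' @param nPerm permutation replicates (default 1000).
#' @param seed RNG seed; identical seed gives identical output.
#' @param minSize,maxSize sets whose intersection with the ranked universe
#'   falls outside `[minSize, maxSize]` are skipped with a warning
#'   (defaults 15 and 500).
#' @return data.frame with columns `set_name`, `size`, `ES`, `NES`,
#'   `p_perm`, `fdr_q`.
#' @export
prerankedGsea <- function(stats, sets, weight = 1, nPerm = 1000, seed = 1,
                          minSize = 15, maxSize = 500) {
  if (!all(is.finite(stats))) stop("ranking statistics must be finite")
  if (is.null(names(stats))) stop("stats must be named by gene")
  ord <- order(-stats, names(stats))
  statsSorted <- stats[ord]
  universe <- names(statsSorted)
  N <- length(universe)

  setGenes <- lapply(sets, function(s)
    if (is(s, "GeneSignature")) s@genes else as.character(s))
  setNamesv <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (is(s, "GeneSignature")) s@name
    else if (!is.null(names(sets)[i]) && nzchar(names(sets)[i])) names(sets)[i]
    else paste0("set", i)
  }, character(1))

  hit.idx <- lapply(setGenes, function(g) which(universe %in% g))
  sizes <- lengths(hit.idx)
  keep <- sizes >= minSize & sizes <= maxSize & sizes < N
  if (any(sizes == 0))
    warning("skipping set(s) with no ranked genes: ",
            paste(setNamesv[sizes == 0], collapse = ", "))
  if (any(!keep & sizes > 0))
    warning("skipping set(s) outside [minSize, maxSize]: ",
            paste(setNamesv[!keep & sizes > 0], collapse = ", "))
  if (!any(keep))
    return(data.frame(set_name = character(0), size = integer(0),
                      ES = numeric(0), NES = numeric(0),
                      p_perm = numeric(0), fdr_q = numeric(0)))
  hit.idx <- hit.idx[keep]
  sizes <- sizes[keep]
  nm <- setNamesv[keep]

  es <- vapply(hit.idx, gseaEnrichmentScore, numeric(1),
               statsSorted = statsSorted, weight = weight)

  # one permutation null per distinct set size (sets of equal size share it)
  null.by.size <- withSeed(seed, {
    out <- list()
    for (sz in sort(unique(sizes))) {
      out[[as.character(sz)]] <- vapply(seq_len(nPerm), function(i)
        gseaEnrichmentScore(statsSorted, sort(sample.int(N, sz)), weight),
        numeric(1))
    }
    out
  })

  nes <- p.perm <- numeric(length(es))
  null.nes <- vector("list", length(es))
  for (i in seq_along(es)) {
    null <- null.by.size[[as.character(sizes[i])]]
    same <- null[sign(null) == sign(es[i]) | es[i] == 0]
    if (length(same) == 0) same <- abs(null)
    denom <- mean(abs(same))
    nes[i] <- es[i] / denom
    p.perm[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
    pos.n <- null[null >= 0]; neg.n <- null[null < 0]
    null.nes[[i]] <- c(if (length(pos.n)) pos.n / mean(pos.n),
                       if (length(neg.n)) -neg.n / mean(-neg.n) * -1)
  }
  all.null.nes <- unlist(null.nes)

  fdr <- vapply(seq_along(es), function(i) {
    if (nes[i] >= 0) {
      num <- mean(all.null.nes[all.null.nes >= 0] >= nes[i])
      den <- mean(nes[nes >= 0] >= nes[i])
    } else {
      num <- mean(all.null.nes[all.null.nes < 0] <= nes[i])
      den <- mean(nes[nes < 0] <= nes[i])
    }
    if (!is.finite(num) || !is.finite(den) || den == 0) return(1)
    min(1, num / den)
  }, numeric(1))

  data.frame(set_name = nm, size = as.integer(sizes), ES = es, NES = nes,
             p_perm = p.perm, fdr_q = fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}
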