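# In-code fixtures shared across test files.

# Small labelled cohort with hand-chosen values.
toyCohort <- function(values, genes = NULL, samples = NULL,
                      nodeStatus = NULL, centered = FALSE) {
  values <- as.matrix(values)
  rownames(values) <- genes %||% sprintf("g%d", seq_len(nrow(values)))
  colnames(values) <- samples %||% sprintf("s%d", seq_len(ncol(values)))
  NodeCohort(values, nodeStatus = nodeStatus, centered = centered)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a small expression TSV and return its path.
writeExprFixture <- function(df, file = tempfile(fileext = ".tsv")) {
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  file
}

# Brute-force AUC oracle: pairwise concordance with half credit for ties.
bruteForceAuc <- function(scores, pos) {
  ip <- which(pos); iq <- which(!pos)
  tot <- 0
  for (i in ip) for (j in iq)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(ip) * length(iq))
}

# Brute-force BH oracle: exhaustive scan of the step-up rule,
# q_(i) = min over j >= i of p_(j) * m / j on the sorted p-values.
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(m),
               function(i) min(ps[i:m] * m / (i:m)), numeric(1))
  q <- numeric(m)
  q[o] <- pmin(1, qs)
  q
}
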