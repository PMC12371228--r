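#' Configuration for the synthetic two-cohort generator
#'
#' Builds and validates the parameter set of the generator. Defaults emulate
#' the study conditions the package is designed around: two bulk-transcriptome
#' cohorts of 300 samples with roughly one third node-positive cases, latent
#' molecular-subtype structure, cohort-specific per-gene location shifts, and
#' a planted node-status signal of which a tunable fraction is shared between
#' cohorts.
#'
#' @param n_genes number of genes (default 5000; scalable to the full
#'   22383-gene universe).
#' @param n_samples_per_cohort samples per cohort (default 300).
#' @param prevalence fraction of `pN+` samples (default 0.34).
#' @param n_signal_genes number of planted signal genes per cohort.
#' @param effect_size_delta mean log2 shift added to a signal gene in `pN+`
#'   samples (sign per gene direction).
#' @param shared_fraction_rho fraction of signal genes common to both
#'   cohorts, in `[0, 1]`.
#' @param n_subtypes number of latent subtypes (default 5).
#' @param subtype_shift_sd SD of subtype-specific gene-mean shifts; each
#'   subtype perturbs a random 20% of genes.
#' @param cohort_shift_sd SD of cohort-specific per-gene location offsets.
#' @param noise_sd residual per-observation SD.
#' @param dropout_rate per-gene probability of being structurally
#'   zero-inflated (a Uniform(0.5, 0.9) fraction of its entries set to 0),
#'   to exercise the zero-fraction filter. Default 0.
#' @param seed integer seed; all draws derive from it.
#' @return a validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(n_genes = 5000, n_samples_per_cohort = 300,
                            prevalence = 0.34, n_signal_genes = 50,
                            effect_size_delta = 1, shared_fraction_rho = 0.5,
                            n_subtypes = 5, subtype_shift_sd = 0.5,
                            cohort_shift_sd = 0.3, noise_sd = 1,
                            dropout_rate = 0, seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_per_cohort = as.integer(n_samples_per_cohort),
              prevalence = prevalence, n_signal_genes = as.integer(n_signal_genes),
              effect_size_delta = effect_size_delta,
              shared_fraction_rho = shared_fraction_rho,
              n_subtypes = as.integer(n_subtypes),
              subtype_shift_sd = subtype_shift_sd,
              cohort_shift_sd = cohort_shift_sd, noise_sd = noise_sd,
              dropout_rate = dropout_rate, seed = as.integer(seed))
  stopifnot(cfg$prevalence >= 0, cfg$prevalence <= 1,
            cfg$shared_fraction_rho >= 0, cfg$shared_fraction_rho <= 1,
            cfg$subtype_shift_sd >= 0, cfg$cohort_shift_sd >= 0,
            cfg$noise_sd >= 0, cfg$dropout_rate >= 0, cfg$dropout_rate <= 1,
            cfg$n_subtypes >= 1)
  if (cfg$n_signal_genes > cfg$n_genes)
    stop("n_signal_genes must not exceed n_genes")
  class(cfg) <- c("SyntheticConfig", "list")
  cfg
}

#' Generate a synthetic pair of expression cohorts with known ground truth
#'
#' Per cohort `c`, sample `j`, gene `g`, the generative model on the log2
#' scale is
#' \deqn{x = \mu_g + B_{g,c} + S_{g,subtype(j)} +
#'   y_j \delta d_g 1[g \in signal(c)] + \epsilon}
#' with gene baseline \eqn{\mu_g \sim N(0,1)} (shared between cohorts),
#' cohort offset \eqn{B \sim N(0, cohort\_shift\_sd)}, subtype effect
#' \eqn{S \sim N(0, subtype\_shift\_sd)} on a random 20% of genes per subtype
#' (shared biology: the same subtype effects act in both cohorts), node
#' status \eqn{y_j \sim Bernoulli(prevalence)}, direction \eqn{d_g = +1} for
#' up and \eqn{-1} for down genes (half each), and noise
#' \eqn{\epsilon \sim N(0, noise\_sd)}. Cohort signal-gene sets share exactly
#' `round(rho * n_signal_genes)` genes. Zero-inflated genes have a
#' Uniform(0.5, 0.9) fraction of entries set to exactly 0 before any
#' centering. The same seed reproduces the output bit for bit.
#'
#' @param config a [syntheticConfig].
#' @return list with elements `cohort1`, `cohort2` (uncentered, labelled
#'   [NodeCohort]s) and `truth`: a list with `signal_genes_cohort1`,
#'   `signal_genes_cohort2`, `per_gene_direction` (named `up`/`down` over all
#'   signal genes), `subtype_assignment` (per-cohort named integer vectors)
#'   and `dropout_genes` (per cohort).
#' @export
simulateCohortPair <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  p <- config$n_genes
  genes <- sprintf("G%05d", seq_len(p))

  truth <- withSeed(deriveSeed(config$seed, "truth"), {
    mu <- rnorm(p)
    n.shared <- round(config$shared_fraction_rho * config$n_signal_genes)
    n.union <- 2L * config$n_signal_genes - n.shared
    pool <- sample(genes, n.union)
    shared <- pool[seq_len(n.shared)]
    own1 <- pool[n.shared + seq_len(config$n_signal_genes - n.shared)]
    own2 <- pool[config$n_signal_genes + seq_len(config$n_signal_genes - n.shared)]
    sig1 <- sort(c(shared, own1))
    sig2 <- sort(c(shared, own2))
    all.sig <- sort(unique(c(sig1, sig2)))
    dir <- setNames(rep("down", length(all.sig)), all.sig)
    dir[sample(seq_along(all.sig), ceiling(length(all.sig) / 2))] <- "up"
    # subtype effects: per subtype, a random 20% of genes are shifted
    S <- matrix(0, p, config$n_subtypes, dimnames = list(genes, NULL))
    for (k in seq_len(config$n_subtypes)) {
      hit <- sample.int(p, round(0.2 * p))
      S[hit, k] <- rnorm(length(hit), sd = config$subtype_shift_sd)
    }
    list(mu = setNames(mu, genes), sig1 = sig1, sig2 = sig2, dir = dir, S = S)
  })

  makeCohort <- function(which.c) {
    sig <- if (which.c == 1L) truth$sig1 else truth$sig2
    withSeed(deriveSeed(config$seed, "cohort", which.c), {
      n <- config$n_samples_per_cohort
      samples <- sprintf("C%d_S%03d", which.c, seq_len(n))
      B <- rnorm(p, sd = config$cohort_shift_sd)
      subtype <- sample.int(config$n_subtypes, n, replace = TRUE)
      y <- rbinom(n, 1L, config$prevalence)
      X <- matrix(rnorm(p * n, sd = config$noise_sd), p, n,
                  dimnames = list(genes, samples))
      X <- X + truth$mu + B + truth$S[, subtype, drop = FALSE]
      d <- ifelse(truth$dir[sig] == "up", 1, -1)
      X[sig, y == 1L] <- X[sig, y == 1L] + config$effect_size_delta * d
      dropout <- character(0)
      if (config$dropout_rate > 0) {
        drop.gene <- which(runif(p) < config$dropout_rate)
        dropout <- genes[drop.gene]
        for (g in drop.gene) {
          frac <- runif(1, 0.5, 0.9)
          X[g, sample.int(n, round(frac * n))] <- 0
        }
      }
      list(cohort = NodeCohort(X, nodeStatus = ifelse(y == 1L, "pN+", "pN0"),
                               cohort = paste0("cohort", which.c),
                               centered = FALSE),
           subtype = setNames(subtype, samples), dropout = dropout)
    })
  }

  c1 <- makeCohort(1L)
  c2 <- makeCohort(2L)
  list(cohort1 = c1$cohort, cohort2 = c2$cohort,
       truth = list(signal_genes_cohort1 = truth$sig1,
                    signal_genes_cohort2 = truth$sig2,
                    per_gene_direction = truth$dir,
                    subtype_assignment = list(cohort1 = c1$subtype,
                                              cohort2 = c2$subtype),
                    dropout_genes = list(cohort1 = c1$dropout,
                                         cohort2 = c2$dropout)))
}

#' Per-gene zero-fraction report
#'
#' Fraction of exactly-zero entries per gene, the quantity behind the
#' low-expression filter (genes with zeros in more than half of the samples
#' are removed before normalisation).
#'
#' @param x a [NodeCohort] or matrix (uncentered values).
#' @return data.frame with columns `gene` and `zero_fraction`.
#' @export
zeroFractionReport <- function(x) {
  m <- if (is(x, "NodeCohort")) exprs2(x) else as.matrix(x)
  data.frame(gene = rownames(m),
             zero_fraction = rowMeans(m == 0),
             row.names = NULL, stringsAsFactors = FALSE)
}
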