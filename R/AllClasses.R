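#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats median pt pnorm var sd rnorm rbinom runif quantile
#'   p.adjust fisher.test phyper wilcox.test t.test ks.test predict coef
#'   setNames complete.cases
#' @importFrom utils read.table write.table head
NULL

#' Expression cohort container
#'
#' `NodeCohort` extends [SummarizedExperiment::SummarizedExperiment] and holds
#' a genes x samples matrix of log2 expression values together with per-sample
#' node-status labels (`pN0` / `pN+`) and a cohort name in `colData`. A single
#' logical flag in `metadata()` records whether each gene has been
#' median-centered across samples; scoring functions that require centered
#' input check this flag.
#'
#' @slot .  inherits all slots from `SummarizedExperiment`.
#' @export
setClass("NodeCohort", contains = "SummarizedExperiment")

setValidity("NodeCohort", function(object) {
  m <- SummarizedExperiment::assay(object, "exprs")
  msgs <- character(0)
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    msgs <- c(msgs, "gene identifiers must be present and unique")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    msgs <- c(msgs, "sample identifiers must be present and unique")
  if (!all(is.finite(m)))
    msgs <- c(msgs, "all expression values must be finite")
  cen <- S4Vectors::metadata(object)$centered
  if (!is.logical(cen) || length(cen) != 1L || is.na(cen))
    msgs <- c(msgs, "metadata()$centered must be TRUE or FALSE")
  if ("node_status" %in% colnames(SummarizedExperiment::colData(object))) {
    ns <- SummarizedExperiment::colData(object)$node_status
    if (!is.factor(ns) || !identical(levels(ns), c("pN0", "pN+")))
      msgs <- c(msgs, "node_status must be a factor with levels pN0, pN+")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a NodeCohort
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample identifiers), log2 scale.
#' @param nodeStatus optional vector of node-status labels, one per sample;
#'   synonyms `N0`/`N1`/`N2`/`N3`/`N+` are normalised to `pN0`/`pN+`.
#'   `NA` marks samples without a label (excluded from label-dependent ops).
#' @param cohort single cohort name stored per sample.
#' @param centered logical; have genes already been median-centered?
#' @return a `NodeCohort`.
#' @export
NodeCohort <- function(values, nodeStatus = NULL, cohort = NA_character_,
                       centered = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  cd <- S4Vectors::DataFrame(row.names = colnames(values))
  cd$cohort <- rep(as.character(cohort), ncol(values))
  if (!is.null(nodeStatus)) {
    stopifnot(length(nodeStatus) == ncol(values))
    cd$node_status <- normalizeNodeStatus(nodeStatus)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = cd,
    metadata = list(centered = isTRUE(centered)))
  new("NodeCohort", se)
}

#' Gene-expression signature
#'
#' A named gene list with per-gene directionality relative to the positive
#' (`pN+`) class: `up`, `down`, or `unknown` when the original report gave no
#' direction.
#'
#' @slot name signature name.
#' @slot genes character vector of unique gene symbols.
#' @slot direction named character vector over `genes` with values
#'   `up`/`down`/`unknown`.
#' @slot source free-text provenance.
#' @export
setClass("GeneSignature",
         representation(name = "character", genes = "character",
                        direction = "character", source = "character"))

setValidity("GeneSignature", function(object) {
  msgs <- character(0)
  if (length(object@genes) == 0L) msgs <- c(msgs, "genes must be non-empty")
  if (anyDuplicated(object@genes)) msgs <- c(msgs, "genes must be unique")
  if (!identical(sort(names(object@direction)), sort(object@genes)))
    msgs <- c(msgs, "direction must be named by exactly the signature genes")
  if (!all(object@direction %in% c("up", "down", "unknown")))
    msgs <- c(msgs, "direction values must be up/down/unknown")
  if (length(msgs)) msgs else TRUE
})

#' @param name signature name.
#' @param genes character vector of gene symbols (whitespace trimmed).
#' @param direction optional named character vector (`up`/`down`/`unknown`);
#'   genes not named default to `unknown`.
#' @param source free-text provenance.
#' @rdname GeneSignature-class
#' @export
GeneSignature <- function(name, genes, direction = NULL, source = "") {
  genes <- trimws(genes)
  dir <- setNames(rep("unknown", length(genes)), genes)
  if (!is.null(direction)) {
    direction <- direction[names(direction) %in% genes]
    dir[names(direction)] <- unname(direction)
  }
  new("GeneSignature", name = as.character(name), genes = genes,
      direction = dir, source = as.character(source))
}

#' Signature matched against a dataset
#'
#' Partition of a signature's genes into those present / absent in an
#' expression matrix, with a resolved direction (and its provenance,
#' `reported` or `inferred`) for matched genes.
#'
#' @slot signature the original [GeneSignature-class].
#' @slot matchedGenes genes found in the dataset.
#' @slot unmatchedGenes genes absent from the dataset.
#' @slot resolvedDirection named character over matched genes; `up`/`down`,
#'   or `NA` while a reported-unknown direction has not yet been inferred.
#' @slot provenance named character over matched genes: `reported`,
#'   `inferred`, or `NA` when unresolved.
#' @export
setClass("MatchedSignature",
         representation(signature = "GeneSignature",
                        matchedGenes = "character",
                        unmatchedGenes = "character",
                        resolvedDirection = "character",
                        provenance = "character"))

setValidity("MatchedSignature", function(object) {
  msgs <- character(0)
  all.genes <- sort(c(object@matchedGenes, object@unmatchedGenes))
  if (!identical(all.genes, sort(object@signature@genes)))
    msgs <- c(msgs, "matched + unmatched must equal the signature genes")
  if (!identical(sort(names(object@resolvedDirection)),
                 sort(object@matchedGenes)))
    msgs <- c(msgs, "resolvedDirection must cover exactly the matched genes")
  ok <- object@resolvedDirection %in% c("up", "down") |
    is.na(object@resolvedDirection)
  if (!all(ok)) msgs <- c(msgs, "resolvedDirection values must be up/down/NA")
  if (length(msgs)) msgs else TRUE
})

#' Gene-list overlap against a chance expectation
#'
#' @slot observed observed overlap (distinct genes in >= 2 lists, or |A∩B|).
#' @slot expected expected overlap under the null (analytic or simulated).
#' @slot analytic first-order analytic expectation (sum of pairwise
#'   `n_i n_j / N`), reported alongside simulation as a cross-check.
#' @slot pValue null tail probability of the observed overlap (or larger).
#' @slot listSizes sizes of the input lists.
#' @slot universeSize size of the gene universe.
#' @slot method `"hypergeometric"` (two lists, analytic + Fisher test) or
#'   `"simulation"` (multi-list redraw null).
#' @slot nSims number of simulation replicates (0 for analytic).
#' @export
setClass("OverlapResult",
         representation(observed = "numeric", expected = "numeric",
                        analytic = "numeric", pValue = "numeric",
                        listSizes = "integer", universeSize = "integer",
                        method = "character", nSims = "integer"))

#' Reproducible repeated stratified fold assignment
#'
#' Assignment of samples to `repeats` x `kOuter` outer folds, each outer
#' training set further split into `kInner` inner folds, stratified by class
#' so per-fold class counts differ from proportionality by at most one
#' sample. The same plan is reused across signatures and methods so that all
#' comparisons share identical partitions.
#'
#' @slot repeats,kOuter,kInner fold-scheme dimensions.
#' @slot sampleIds sample identifiers, in matrix column order.
#' @slot outer integer matrix (samples x repeats) of outer fold ids.
#' @slot inner nested list: `inner[[repeat]][[outerFold]]` is a named integer
#'   vector of inner fold ids over that outer training set.
#' @slot seed the seed the plan was built from.
#' @export
setClass("FoldPlan",
         representation(repeats = "integer", kOuter = "integer",
                        kInner = "integer", sampleIds = "character",
                        outer = "matrix", inner = "list", seed = "integer"))

#' Cross-validation evaluation result
#'
#' @slot perFold data.frame with one row per (repeat, outer fold): AUC,
#'   balanced accuracy, number of selected features, degenerate flag, and a
#'   list-column of the selected feature names (the audit trail).
#' @slot meanAuc,sdAuc,meanBalancedAccuracy aggregates over non-skipped folds.
#' @slot degenerateFolds folds whose tuned model retained zero features.
#' @slot skippedFolds outer folds skipped because the test fold had one class.
#' @slot leaky TRUE when feature selection ran once on the full dataset
#'   before cross-validation (the information-leakage contrast).
#' @slot fsMethod feature-selection method, or `"fixed_signature"`.
#' @export
setClass("CVResult",
         representation(perFold = "data.frame", meanAuc = "numeric",
                        sdAuc = "numeric", meanBalancedAccuracy = "numeric",
                        degenerateFolds = "integer", skippedFolds = "integer",
                        leaky = "logical", fsMethod = "character"))

#' Fitted classification model
#'
#' @slot family `elastic_net_logistic` or `random_forest`.
#' @slot features input feature names, in training order.
#' @slot selectedFeatures features retained by the fitted model.
#' @slot model the underlying `glmnet` or `ranger` fit.
#' @slot chosenAlpha,chosenLambda tuned elastic-net hyperparameters (NA for
#'   random forest).
#' @slot center,scale per-feature standardisation parameters estimated on the
#'   training data and re-applied at prediction time.
#' @slot degenerate TRUE when the tuned elastic net retained zero features;
#'   such a model predicts the constant training prevalence.
#' @slot prevalence training-class prevalence (the degenerate prediction).
#' @slot trainingAuc apparent AUC on the training data.
#' @export
setClass("FitResult",
         representation(family = "character", features = "character",
                        selectedFeatures = "character", model = "ANY",
                        chosenAlpha = "numeric", chosenLambda = "numeric",
                        center = "numeric", scale = "numeric",
                        degenerate = "logical", prevalence = "numeric",
                        trainingAuc = "numeric"))
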