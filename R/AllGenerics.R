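#' @describeIn NodeCohort-class expression matrix accessor (genes x samples).
#' @param x a `NodeCohort`.
#' @export
exprs2 <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn NodeCohort-class has each gene been median-centered?
#' @export
isCentered <- function(x) isTRUE(S4Vectors::metadata(x)$centered)

#' @describeIn NodeCohort-class node-status labels (factor pN0/pN+, NA where
#'   unknown), or NULL when the cohort carries no labels.
#' @export
nodeStatus <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("node_status" %in% colnames(cd)) cd$node_status else NULL
}

#' @describeIn NodeCohort-class cohort name (first per-sample value).
#' @export
cohortName <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("cohort" %in% colnames(cd) && ncol(x) > 0) cd$cohort[1] else NA_character_
}

#' @describeIn GeneSignature-class gene symbols of a signature.
#' @param object a `GeneSignature`.
#' @export
signatureGenes <- function(object) object@genes

#' @describeIn GeneSignature-class per-gene direction (up/down/unknown).
#' @export
signatureDirection <- function(object) object@direction

#' @describeIn MatchedSignature-class genes present in the dataset.
#' @param object a `MatchedSignature`.
#' @export
matchedGenes <- function(object) object@matchedGenes

#' @describeIn MatchedSignature-class genes absent from the dataset.
#' @export
unmatchedGenes <- function(object) object@unmatchedGenes

#' @describeIn MatchedSignature-class resolved per-gene direction
#'   (up/down, NA while unresolved).
#' @export
resolvedDirection <- function(object) object@resolvedDirection

#' @describeIn MatchedSignature-class direction provenance
#'   (reported/inferred).
#' @export
directionProvenance <- function(object) object@provenance

#' @export
setMethod("show", "GeneSignature", function(object) {
  tab <- table(factor(object@direction, c("up", "down", "unknown")))
  cat("GeneSignature \"", object@name, "\": ", length(object@genes),
      " genes (up ", tab[["up"]], ", down ", tab[["down"]],
      ", unknown ", tab[["unknown"]], ")\n", sep = "")
  if (nzchar(object@source)) cat("  source: ", object@source, "\n", sep = "")
})

#' @export
setMethod("show", "MatchedSignature", function(object) {
  cat("MatchedSignature \"", object@signature@name, "\": ",
      length(object@matchedGenes), "/", length(object@signature@genes),
      " genes matched", sep = "")
  unres <- sum(is.na(object@resolvedDirection))
  if (unres > 0) cat("; ", unres, " direction(s) unresolved", sep = "")
  cat("\n")
})

#' @export
setMethod("show", "OverlapResult", function(object) {
  cat("OverlapResult (", object@method, "): observed ", object@observed,
      ", expected ", signif(object@expected, 4), sep = "")
  if (!is.na(object@pValue)) cat(", p = ", signif(object@pValue, 3), sep = "")
  cat("\n  lists of sizes ", paste(object@listSizes, collapse = ", "),
      " in universe of ", object@universeSize, "\n", sep = "")
})

#' @export
setMethod("show", "FoldPlan", function(object) {
  cat("FoldPlan: ", length(object@sampleIds), " samples, ",
      object@repeats, " repeat(s) x ", object@kOuter, " outer x ",
      object@kInner, " inner folds (seed ", object@seed, ")\n", sep = "")
})

#' @export
setMethod("show", "CVResult", function(object) {
  cat("CVResult (", if (object@leaky) "LEAKY selection" else "nested selection",
      ", fs = ", object@fsMethod, "): ", nrow(object@perFold),
      " outer folds\n", sep = "")
  cat("  mean AUC ", round(object@meanAuc, 3), " (sd ",
      round(object@sdAuc, 3), "), mean balanced accuracy ",
      round(object@meanBalancedAccuracy, 3), "\n", sep = "")
  if (object@degenerateFolds > 0)
    cat("  ", object@degenerateFolds, " degenerate fold(s)\n", sep = "")
  if (object@skippedFolds > 0)
    cat("  ", object@skippedFolds, " skipped fold(s)\n", sep = "")
})

#' @export
setMethod("show", "FitResult", function(object) {
  cat("FitResult (", object@family, "): ", length(object@selectedFeatures),
      "/", length(object@features), " features retained", sep = "")
  if (object@family == "elastic_net_logistic")
    cat(", alpha = ", object@chosenAlpha, ", lambda = ",
        signif(object@chosenLambda, 3), sep = "")
  if (object@degenerate) cat(" [degenerate]")
  cat("; training AUC ", round(object@trainingAuc, 3), "\n", sep = "")
})
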