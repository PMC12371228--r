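#' Pipeline configuration
#'
#' Assembles and validates the configuration for [runPipeline]. Exactly one
#' input source must be given: a [syntheticConfig] (the generator supplies
#' two cohorts with ground truth) or a pair of on-disk cohorts (expression +
#' metadata paths). Defaults mirror the package's standard protocol: 5 outer
#' x 5 inner folds, 10 elastic-net / 5 random-forest repeats, alpha grid 0
#' to 1 in 0.05 steps, top-100 gene selection, top-25 up + top-25 down DEG
#' signatures, and overlap fractions 0.1%, 1%, 5%, 10%.
#'
#' @param synthetic a [syntheticConfig], or `NULL`.
#' @param cohortPaths list with `expr1`, `meta1`, `expr2`, `meta2` file
#'   paths, or `NULL`.
#' @param signatures list of [GeneSignature-class], or a GMT file path, or
#'   `NULL` (step 1 and the signature-overlap null are then skipped).
#' @param fractions top-list fractions for the cross-cohort DE overlap.
#' @param topK DEG signature size per direction (default 25).
#' @param fsMethods feature-selection methods contrasted in step 3.
#' @param families model families evaluated in step 1.
#' @param alphaGrid elastic-net mixing grid used by every model in the
#'   pipeline (default 0 to 1 in 0.05 steps).
#' @param enetRepeats,rfRepeats CV repeats per family (defaults 10 and 5).
#' @param cvRepeats repeats for the step-3 nested/leaky contrast (default 1
#'   to keep the de-novo stage affordable; raise to 10 for the full
#'   protocol).
#' @param kOuter,kInner fold counts (defaults 5 and 5).
#' @param selectK genes kept by t-test / Wilcoxon / RF-importance selection.
#' @param gseaSets optional list of gene sets for pre-ranked GSEA in step 2.
#' @param gseaPerm GSEA permutations (default 1000).
#' @param nSimsOverlap replicates for the multi-signature overlap null.
#' @param steps subset of `1:3` to run.
#' @param seed global seed; every random draw derives from it.
#' @param outdir optional directory; when given, intermediates (expression,
#'   DE tables, per-fold results, report JSON) are written there.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(synthetic = NULL, cohortPaths = NULL,
                           signatures = NULL,
                           fractions = c(0.001, 0.01, 0.05, 0.1),
                           topK = 25,
                           fsMethods = c("embedded_enet", "t_test",
                                         "wilcoxon", "rf_importance"),
                           families = c("elastic_net_logistic",
                                        "random_forest"),
                           alphaGrid = seq(0, 1, by = 0.05),
                           enetRepeats = 10, rfRepeats = 5, cvRepeats = 1,
                           kOuter = 5, kInner = 5, selectK = 100,
                           gseaSets = NULL, gseaPerm = 1000,
                           nSimsOverlap = 10000, steps = 1:3, seed = 1,
                           outdir = NULL) {
  if (is.null(synthetic) == is.null(cohortPaths))
    stop("exactly one of synthetic / cohortPaths must be given")
  stopifnot(all(fractions > 0 & fractions <= 1))
  cfg <- as.list(environment())
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

.writeIf <- function(outdir, name, obj) {
  if (is.null(outdir)) return(invisible(NULL))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  path <- file.path(outdir, name)
  if (is.data.frame(obj)) {
    flat <- obj[, !vapply(obj, is.list, logical(1)), drop = FALSE]
    write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  invisible(path)
}

cvSummaryRow <- function(res) {
  data.frame(mean_auc = res@meanAuc, sd_auc = res@sdAuc,
             mean_balanced_accuracy = res@meanBalancedAccuracy,
             degenerate_folds = res@degenerateFolds,
             skipped_folds = res@skippedFolds, stringsAsFactors = FALSE)
}

#' Run the three-step evaluation workflow
#'
#' End-to-end orchestration over two cohorts: preprocessing (zero-fraction
#' filter, per-gene median centering, restriction to the shared gene
#' universe), then
#' step 1 — score every supplied signature in both cohorts (mean signature
#' score AUC with data-driven directionality where needed, plus repeated
#' nested CV of each model family on the signature's genes);
#' step 2 — moderated-t differential expression per cohort, cross-cohort
#' overlap of top up-/down-lists at the configured fractions against the
#' hypergeometric expectation, the multi-signature overlap null, and
#' optional pre-ranked GSEA;
#' step 3 — top-k DEG signatures cross-applied between cohorts (mean-score
#' AUCs and fixed-signature CV), the nested-versus-leaky feature-selection
#' contrast per method, and final full-cohort models applied to the opposite
#' cohort.
#' The same seed reproduces the report exactly.
#'
#' @param config a [pipelineConfig].
#' @return list of class `sigleakReport` with elements `data` (gene/sample
#'   bookkeeping), `step1`, `step2`, `step3`, `truth` (for synthetic input)
#'   and `provenance`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  seed <- config$seed
  report <- list(provenance = list(
    seed = seed,
    package_version = as.character(utils::packageVersion("sigleak")),
    steps = config$steps))

  # ---- inputs ---------------------------------------------------------
  if (!is.null(config$synthetic)) {
    sim <- simulateCohortPair(config$synthetic)
    cohorts <- list(cohort1 = sim$cohort1, cohort2 = sim$cohort2)
    report$truth <- sim$truth
  } else {
    p <- config$cohortPaths
    c1 <- attachLabels(readExpressionMatrix(p$expr1, cohort = "cohort1"),
                       readSampleTable(p$meta1))
    c2 <- attachLabels(readExpressionMatrix(p$expr2, cohort = "cohort2"),
                       readSampleTable(p$meta2))
    cohorts <- list(cohort1 = c1, cohort2 = c2)
  }
  sigs <- config$signatures
  if (is.character(sigs)) sigs <- readGmt(sigs)

  # ---- preprocessing: filter, center, shared universe -----------------
  n.before <- vapply(cohorts, nrow, integer(1))
  cohorts <- lapply(cohorts, filterLowExpression)
  shared <- intersect(rownames(cohorts$cohort1), rownames(cohorts$cohort2))
  cohorts <- lapply(cohorts, function(x) medianCenter(x[shared, ]))
  message("shared gene universe after filtering: ", length(shared),
          " genes (from ", paste(n.before, collapse = "/"), ")")
  report$data <- list(
    n_genes_input = as.list(n.before),
    n_genes_universe = length(shared),
    n_samples = lapply(cohorts, ncol),
    n_positive = lapply(cohorts, function(x)
      sum(nodeStatus(x) == "pN+", na.rm = TRUE)))

  labelled <- lapply(cohorts, function(x) x[, !is.na(nodeStatus(x))])

  # ---- step 1: signature scoring + fixed-signature models -------------
  if (1 %in% config$steps && length(sigs)) {
    score.rows <- list(); cv.rows <- list()
    for (cn in names(labelled)) {
      x <- labelled[[cn]]
      for (s in sigs) {
        ms <- inferDirectionality(matchSignature(s, x), x)
        sc <- meanSignatureScore(ms, x)
        score.rows[[length(score.rows) + 1L]] <- data.frame(
          cohort = cn, signature = s@name,
          n_matched = length(ms@matchedGenes),
          n_inferred = sum(ms@provenance == "inferred", na.rm = TRUE),
          score_auc = rocAuc(sc, nodeStatus(x))$auc,
          stringsAsFactors = FALSE)
        for (fam in config$families) {
          reps <- if (fam == "elastic_net_logistic") config$enetRepeats
                  else config$rfRepeats
          plan <- makeFoldPlan(nodeStatus(x), kOuter = config$kOuter,
                               kInner = config$kInner, repeats = reps,
                               seed = deriveSeed(seed, "plan", cn, fam),
                               sampleIds = colnames(x))
          res <- nestedCvEvaluate(x,
                                  spec = modelSpec(family = fam,
                                                   alphaGrid = config$alphaGrid),
                                  plan = plan, signature = s,
                                  seed = deriveSeed(seed, "s1", cn, s@name,
                                                    fam))
          cv.rows[[length(cv.rows) + 1L]] <- cbind(
            data.frame(cohort = cn, signature = s@name, family = fam,
                       stringsAsFactors = FALSE),
            cvSummaryRow(res))
        }
      }
    }
    report$step1 <- list(scores = do.call(rbind, score.rows),
                         models = do.call(rbind, cv.rows))
    .writeIf(config$outdir, "step1_scores.tsv", report$step1$scores)
    .writeIf(config$outdir, "step1_models.tsv", report$step1$models)
  }

  # ---- step 2: DE, overlap, GSEA --------------------------------------
  if (2 %in% config$steps) {
    de <- lapply(labelled, differentialExpression)
    m.univ <- length(shared)
    ov.rows <- list()
    for (fr in config$fractions) {
      for (dir in c("up", "down")) {
        lA <- topGeneLists(de$cohort1, direction = dir, fraction = fr)
        lB <- topGeneLists(de$cohort2, direction = dir, fraction = fr)
        ov <- listOverlapTest(lA, lB, m.univ)
        ov.rows[[length(ov.rows) + 1L]] <- data.frame(
          fraction = fr, direction = dir, list_size_1 = length(lA),
          list_size_2 = length(lB), observed = ov@observed,
          expected = ov@expected, p_value = ov@pValue,
          stringsAsFactors = FALSE)
      }
    }
    step2 <- list(de = de, overlap = do.call(rbind, ov.rows))
    if (length(sigs) >= 2) {
      matched <- lapply(sigs, function(s)
        intersect(s@genes, shared))
      matched <- matched[lengths(matched) > 0]
      step2$signature_overlap <- signatureOverlap(
        matched, universeSize = m.univ, nSims = config$nSimsOverlap,
        seed = deriveSeed(seed, "sigov"))
    }
    if (!is.null(config$gseaSets)) {
      step2$gsea <- lapply(de, function(d)
        prerankedGsea(setNames(d$t_mod, d$gene), config$gseaSets,
                      nPerm = config$gseaPerm,
                      seed = deriveSeed(seed, "gsea")))
    }
    report$step2 <- step2
    .writeIf(config$outdir, "step2_de_cohort1.tsv", de$cohort1)
    .writeIf(config$outdir, "step2_de_cohort2.tsv", de$cohort2)
    .writeIf(config$outdir, "step2_overlap.tsv", step2$overlap)
  }

  # ---- step 3: DEG signatures, nested vs leaky, cross application -----
  if (3 %in% config$steps) {
    if (is.null(report$step2))
      de <- lapply(labelled, differentialExpression)
    else de <- report$step2$de
    deg.sigs <- lapply(names(de), function(cn) {
      up <- topGeneLists(de[[cn]], direction = "up", k = config$topK)
      down <- topGeneLists(de[[cn]], direction = "down", k = config$topK)
      GeneSignature(paste0("top", config$topK, "_", cn), c(up, down),
                    direction = setNames(rep(c("up", "down"),
                                             c(length(up), length(down))),
                                         c(up, down)),
                    source = paste("top DEGs of", cn))
    })
    names(deg.sigs) <- names(de)

    score.rows <- list(); model.rows <- list()
    for (src in names(deg.sigs)) {
      for (tgt in names(labelled)) {
        x <- labelled[[tgt]]
        ms <- matchSignature(deg.sigs[[src]], x)
        sc <- meanSignatureScore(ms, x)
        score.rows[[length(score.rows) + 1L]] <- data.frame(
          signature_from = src, applied_to = tgt,
          score_auc = rocAuc(sc, nodeStatus(x))$auc,
          stringsAsFactors = FALSE)
        plan <- makeFoldPlan(nodeStatus(x), kOuter = config$kOuter,
                             kInner = config$kInner,
                             repeats = config$cvRepeats,
                             seed = deriveSeed(seed, "degplan", src, tgt),
                             sampleIds = colnames(x))
        res <- nestedCvEvaluate(x, spec = modelSpec(alphaGrid = config$alphaGrid),
                                plan = plan, signature = deg.sigs[[src]],
                                seed = deriveSeed(seed, "degcv", src, tgt))
        model.rows[[length(model.rows) + 1L]] <- cbind(
          data.frame(signature_from = src, applied_to = tgt,
                     stringsAsFactors = FALSE),
          cvSummaryRow(res))
      }
    }

    nested.leaky <- list(); final.rows <- list()
    for (cn in names(labelled)) {
      x <- labelled[[cn]]
      plan <- makeFoldPlan(nodeStatus(x), kOuter = config$kOuter,
                           kInner = config$kInner,
                           repeats = config$cvRepeats,
                           seed = deriveSeed(seed, "dnplan", cn),
                           sampleIds = colnames(x))
      pspec <- modelSpec(alphaGrid = config$alphaGrid)
      for (fs in config$fsMethods) {
        nested <- nestedCvEvaluate(x, spec = pspec, plan = plan,
                                   fsMethod = fs, k = config$selectK,
                                   seed = deriveSeed(seed, "dn", cn, fs))
        leaky <- leakyEvaluate(x, spec = pspec, plan = plan, fsMethod = fs,
                               k = config$selectK,
                               seed = deriveSeed(seed, "dn", cn, fs))
        other <- setdiff(names(labelled), cn)
        fin <- trainFinalAndApply(x, labelled[[other]], spec = pspec,
                                  fsMethod = fs, k = config$selectK,
                                  kInner = config$kInner,
                                  seed = deriveSeed(seed, "fin", cn, fs))
        nested.leaky[[paste(cn, fs, sep = ".")]] <-
          list(nested = nested, leaky = leaky)
        final.rows[[length(final.rows) + 1L]] <- data.frame(
          trained_on = cn, fs_method = fs,
          training_auc = fin$trainingAuc, external_auc = fin$externalAuc,
          n_features = length(fin$genesUsed), stringsAsFactors = FALSE)
      }
    }
    report$step3 <- list(deg_signatures = deg.sigs,
                         deg_scores = do.call(rbind, score.rows),
                         deg_models = do.call(rbind, model.rows),
                         nested_vs_leaky = nested.leaky,
                         final_models = do.call(rbind, final.rows))
    .writeIf(config$outdir, "step3_deg_scores.tsv", report$step3$deg_scores)
    .writeIf(config$outdir, "step3_final_models.tsv",
             report$step3$final_models)
  }

  class(report) <- c("sigleakReport", "list")
  if (!is.null(config$outdir)) {
    summ <- list(provenance = report$provenance, data = report$data)
    if (!is.null(report$step3))
      summ$final_models <- report$step3$final_models
    .writeIf(config$outdir, "report.json", summ)
  }
  report
}

#' Summarise the information-leakage gap
#'
#' Per feature-selection method and cohort: mean nested AUC, mean leaky
#' AUC, their gap (leaky minus nested), and — when a final cross-applied
#' model is available — its external AUC.
#'
#' @param report a `sigleakReport` from [runPipeline] containing step 3 with
#'   both nested and leaky arms.
#' @return data.frame with columns `cohort`, `fs_method`, `nested_auc`,
#'   `leaky_auc`, `gap`, `external_auc`.
#' @export
summarizeLeakageGap <- function(report) {
  nl <- report$step3$nested_vs_leaky
  if (is.null(nl) || length(nl) == 0)
    stop("report contains no nested-versus-leaky results")
  rows <- lapply(names(nl), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    arm <- nl[[key]]
    if (is.null(arm$nested) || is.null(arm$leaky))
      stop("missing nested or leaky arm for ", key)
    ext <- NA_real_
    fm <- report$step3$final_models
    if (!is.null(fm)) {
      hit <- fm$trained_on == parts[1] & fm$fs_method == parts[2]
      if (any(hit)) ext <- fm$external_auc[which(hit)[1]]
    }
    data.frame(cohort = parts[1], fs_method = parts[2],
               nested_auc = arm$nested@meanAuc,
               leaky_auc = arm$leaky@meanAuc,
               gap = arm$leaky@meanAuc - arm$nested@meanAuc,
               external_auc = ext, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
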