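#' Read a gene-level expression matrix
#'
#' Reads a delimited text file with gene symbols in the first column and one
#' header row of sample identifiers, producing an (uncentered) [NodeCohort].
#' Gene symbols are matched case-sensitively after whitespace trimming.
#' Duplicate gene rows are collapsed by their mean, with a message reporting
#' how many rows were collapsed.
#'
#' @param path file path (tab- or comma-separated; the separator is sniffed
#'   from the header line unless given).
#' @param sep field separator; default `NULL` sniffs `\t` vs `,`.
#' @param cohort cohort name recorded in the result.
#' @return a [NodeCohort] with `centered = FALSE`.
#' @export
readExpressionMatrix <- function(path, sep = NULL, cohort = NA_character_) {
  header <- readLines(path, n = 1L)
  if (is.null(sep))
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "\"",
                    comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression file needs a gene column plus >= 1 sample")
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample identifier(s) in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  genes <- trimws(raw[[1L]])
  vals <- matrix(NA_real_, nrow(raw), length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric value ", sQuote(raw[[j + 1L]][bad[1L]]),
           " for gene ", sQuote(genes[bad[1L]]),
           " in sample ", sQuote(samples[j]))
    vals[, j] <- v
  }
  if (anyDuplicated(genes)) {
    ndup <- sum(duplicated(genes))
    message("collapsing ", ndup, " duplicate gene row(s) by mean")
    vals <- rowsum(vals, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  rownames(vals) <- genes
  NodeCohort(vals, cohort = cohort, centered = FALSE)
}

#' Write an expression matrix as TSV
#'
#' Column order: `gene`, then the sample identifiers. Values are written with
#' full precision (`format = "%.17g"`-equivalent via `as.character`) so that a
#' write/read round trip is bit-exact.
#'
#' @param x a [NodeCohort] or plain matrix with dimnames.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(x, path) {
  m <- if (is(x, "NodeCohort")) exprs2(x) else as.matrix(x)
  df <- data.frame(gene = rownames(m),
                   vapply(seq_len(ncol(m)),
                          function(j) format(m[, j], digits = 17, trim = TRUE),
                          character(nrow(m))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' Standard GMT: one set per line, `name TAB description TAB gene TAB gene...`.
#' Per-gene directionality may be encoded in the gene fields with the
#' convention `GENE|up` / `GENE|down`; undecorated genes get direction
#' `unknown`. The description field is stored as the signature's source.
#'
#' @param path GMT file path.
#' @return list of [GeneSignature-class] objects, named by signature name.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(list())
  }
  sigs <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    genes.raw <- trimws(fields[-(1:2)])
    genes.raw <- genes.raw[nzchar(genes.raw)]
    has.dir <- grepl("\\|(up|down)$", genes.raw)
    genes <- sub("\\|(up|down)$", "", genes.raw)
    dir <- setNames(rep("unknown", length(genes)), genes)
    dir[has.dir] <- sub("^.*\\|", "", genes.raw[has.dir])
    GeneSignature(name = fields[1L], genes = genes, direction = dir,
                  source = fields[2L])
  })
  names(sigs) <- vapply(sigs, function(s) s@name, character(1))
  sigs
}

#' Write gene signatures to a GMT file
#'
#' Directions other than `unknown` are encoded as `GENE|up` / `GENE|down`.
#'
#' @param signatures list of [GeneSignature-class].
#' @param path output path.
#' @export
writeGmt <- function(signatures, path) {
  lines <- vapply(signatures, function(s) {
    g <- s@genes
    dir <- s@direction[g]
    g <- ifelse(dir == "unknown", g, paste0(g, "|", dir))
    paste(c(s@name, if (nzchar(s@source)) s@source else "na", g),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Delimited text with at least `sample_id` and `node_status` columns.
#' Node-status labels are normalised to the canonical `pN0` / `pN+` levels
#' from documented synonyms (`N0` -> `pN0`; `N+`, `N1`, `N2`, `N3` -> `pN+`).
#' Rows with a missing label are excluded; the exclusion count is reported in
#' a message and stored in the `n_excluded` attribute.
#'
#' @param path file path (separator sniffed: tab vs comma).
#' @param sep optional explicit separator.
#' @return data.frame with columns `sample_id`, `node_status` (factor
#'   `pN0`/`pN+`) and `cohort` (NA when absent from the file), attribute
#'   `n_excluded`.
#' @export
readSampleTable <- function(path, sep = NULL) {
  header <- readLines(path, n = 1L)
  if (is.null(sep))
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character", quote = "\"",
                   comment.char = "", stringsAsFactors = FALSE)
  need <- c("sample_id", "node_status")
  if (!all(need %in% colnames(df)))
    stop("sample table must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id value(s)")
  status <- normalizeNodeStatus(df$node_status)
  keep <- !is.na(status)
  n.excluded <- sum(!keep)
  if (n.excluded > 0)
    message("excluded ", n.excluded, " sample(s) with missing node_status")
  out <- data.frame(sample_id = df$sample_id[keep],
                    node_status = status[keep],
                    cohort = if ("cohort" %in% colnames(df))
                      df$cohort[keep] else NA_character_,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n.excluded
  out
}

#' Attach sample labels to a cohort
#'
#' Joins a sample table (as from [readSampleTable]) onto a [NodeCohort] by
#' sample identifier. Samples without a label keep `NA` and are ignored by
#' label-dependent operations.
#'
#' @param x a [NodeCohort].
#' @param sampleTable data.frame with `sample_id` and `node_status`.
#' @return the labelled [NodeCohort].
#' @export
attachLabels <- function(x, sampleTable) {
  idx <- match(colnames(x), sampleTable$sample_id)
  SummarizedExperiment::colData(x)$node_status <-
    factor(as.character(sampleTable$node_status)[idx],
           levels = c("pN0", "pN+"))
  validObject(x)
  x
}
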