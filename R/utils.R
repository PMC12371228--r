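# Internal helpers shared across modules.

# Deterministic sub-seed derivation: one user-visible seed governs every
# random draw; components derive their own substream seed from (seed, tag)
# so adding a stage never shifts the draws of another. Result < 2^31 - 1.
deriveSeed <- function(seed, ...) {
  tag <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  ints <- utf8ToInt(tag)
  h <- sum(ints * seq_along(ints)) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h * 9349) %% 2147483629 + 1)
}

# Run an expression under a local RNG state so callers' streams are untouched.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Normalise node-status labels to the canonical pN0 / pN+ factor.
# Accepted synonyms are fixed and documented; anything else errors.
.nodeSynonyms <- list(
  "pN0" = c("pN0", "N0", "n0", "pn0", "0", "negative", "node_negative"),
  "pN+" = c("pN+", "N+", "pn+", "n+", "N1", "N2", "N3", "pN1", "pN2", "pN3",
            "1", "positive", "node_positive")
)

normalizeNodeStatus <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_character_, length(x))
  for (lev in names(.nodeSynonyms)) {
    out[x %in% .nodeSynonyms[[lev]]] <- lev
  }
  missing <- is.na(x) | x == "" | toupper(x) == "NA"
  bad <- !missing & is.na(out)
  if (any(bad)) {
    stop("unknown node_status value(s): ",
         paste(unique(x[bad]), collapse = ", "),
         "; accepted synonyms: ",
         paste(unlist(.nodeSynonyms), collapse = ", "))
  }
  out[missing] <- NA_character_
  factor(out, levels = c("pN0", "pN+"))
}

# Coerce assorted label inputs (factor pN0/pN+, 0/1, logical) to logical
# "is positive class".
asPositive <- function(labels) {
  if (is.factor(labels)) {
    if (!all(levels(labels) %in% c("pN0", "pN+")))
      stop("factor labels must have levels pN0/pN+")
    return(labels == "pN+")
  }
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  if (is.character(labels)) return(normalizeNodeStatus(labels) == "pN+")
  stop("unsupported label type")
}
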