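# Embedding providers and pooling compositions. Real transformer encoders
# (token-level biomedical BERT variants, document-level encoders) plug in
# behind the EmbeddingProvider contract; the package ships a deterministic
# hash-based provider so the whole pipeline runs without model weights.

#' Deterministic hash-based embedding provider
#'
#' Maps every token (or whole document) to a fixed pseudo-random vector
#' derived only from the string content, the dimension and the seed, so
#' identical corpora always give identical feature matrices. Entries are
#' approximately standard normal. The provider satisfies the
#' [EmbeddingProvider-class] contract and stands in for transformer
#' adapters in tests and offline runs.
#'
#' @param dim embedding dimension d (default 768, the usual transformer
#'   hidden size).
#' @param seed integer mixed into the hash.
#' @param kind `"token_level"` (one vector per token) or
#'   `"document_level"` (one vector per record, hashing title + abstract).
#' @return An [EmbeddingProvider-class].
#' @examples
#' p <- hashEmbeddingProvider(dim = 4, seed = 1)
#' p@encode(c("clearance", "half-life"))
#' @export
hashEmbeddingProvider <- function(dim = 768L, seed = 0L,
                                  kind = c("token_level", "document_level")) {
  kind <- match.arg(kind)
  dim <- as.integer(dim)
  seed <- as.integer(seed)
  cache <- new.env(parent = emptyenv())
  vecFor <- function(s) {
    key <- s
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    h <- strtoi(substr(digest::digest(c(seed, s), algo = "xxhash32"), 1, 7),
                base = 16L)
    # counter-based pseudo-random values: uniform -> standard normal
    k <- seq_len(dim)
    u <- (sin(h * 0.0007297 + k * 2.399963) * 43758.5453123) %% 1
    u <- pmin(pmax(u, 1e-9), 1 - 1e-9)
    v <- qnorm(u)
    cache[[key]] <- v
    v
  }
  encode <- if (kind == "token_level") {
    function(tokens) {
      if (length(tokens) == 0L)
        return(matrix(numeric(), nrow = 0L, ncol = dim))
      do.call(rbind, lapply(tokens, vecFor))
    }
  } else {
    function(title, abstract) vecFor(paste(title, abstract, sep = "\n"))
  }
  new("EmbeddingProvider",
      id = sprintf("hash-%s-d%d-s%d", kind, dim, seed),
      kind = kind, dim = dim, encode = encode, deterministic = TRUE)
}

.poolCheck <- function(titleEmb, abstractEmb) {
  if (!is.matrix(titleEmb) || !is.matrix(abstractEmb))
    stop("embedding sets must be matrices (tokens x dimensions)")
  if (ncol(titleEmb) != ncol(abstractEmb))
    stop("dimension mismatch: title d = ", ncol(titleEmb),
         ", abstract d = ", ncol(abstractEmb))
  if ((nrow(titleEmb) && any(!is.finite(titleEmb))) ||
      (nrow(abstractEmb) && any(!is.finite(abstractEmb))))
    stop("embedding sets must be finite")
  ncol(titleEmb)
}

.fieldPool <- function(emb, stats) {
  d <- ncol(emb)
  if (nrow(emb) == 0L) return(rep(0, d * length(stats)))
  parts <- lapply(stats, function(s) apply(emb, 2L, s))
  unlist(parts, use.names = FALSE)
}

#' Mean pooling of title and abstract token embeddings
#'
#' Concatenates the per-dimension mean over title tokens with the mean over
#' abstract tokens, giving a `2d`-dimensional document vector (1536 for
#' d = 768). A field with no tokens contributes a zero sub-vector.
#'
#' @param titleEmb,abstractEmb numeric matrices, tokens x d (0 rows
#'   allowed).
#' @return numeric vector of length `2 * d`.
#' @export
poolMean <- function(titleEmb, abstractEmb) {
  .poolCheck(titleEmb, abstractEmb)
  c(.fieldPool(titleEmb, list(mean)), .fieldPool(abstractEmb, list(mean)))
}

#' Mean + min/max pooling of title and abstract token embeddings
#'
#' Per field, concatenates the element-wise mean, minimum and maximum over
#' tokens; the two fields are then concatenated, giving `6d` dimensions
#' (4608 for d = 768). Empty fields contribute zeros.
#'
#' @param titleEmb,abstractEmb numeric matrices, tokens x d.
#' @return numeric vector of length `6 * d`, ordered
#'   (title mean, title min, title max, abstract mean, abstract min,
#'   abstract max).
#' @export
poolMeanMinMax <- function(titleEmb, abstractEmb) {
  .poolCheck(titleEmb, abstractEmb)
  stats <- list(mean, min, max)
  c(.fieldPool(titleEmb, stats), .fieldPool(abstractEmb, stats))
}

#' Pooled document representations for a corpus
#'
#' For a token-level provider, encodes the raw tokenised title and abstract
#' (surface forms, un-stemmed and un-masked, since encoders expect them)
#' and pools with the requested composition; for a document-level provider,
#' passes through the provider's single vector. Output dimension is `2d`
#' for `"mean"`, `6d` for `"mean_minmax"` and `d` for `"doc_level"`.
#'
#' @param corpus a [DocumentCorpus-class].
#' @param provider an [EmbeddingProvider-class].
#' @param mode `"mean"`, `"mean_minmax"` or `"doc_level"`; must be
#'   compatible with the provider kind.
#' @param tokenizer tokenizer for token-level providers, default
#'   [tokenizeField()].
#' @return numeric matrix, documents x output dimension.
#' @export
embedDocument <- function(corpus, provider,
                          mode = c("mean", "mean_minmax", "doc_level"),
                          tokenizer = tokenizeField) {
  stopifnot(is(corpus, "DocumentCorpus"), is(provider, "EmbeddingProvider"))
  mode <- match.arg(mode)
  if (mode == "doc_level" && provider@kind != "document_level")
    stop("mode 'doc_level' requires a document_level provider, got ",
         provider@kind)
  if (mode != "doc_level" && provider@kind != "token_level")
    stop("mode '", mode, "' requires a token_level provider, got ",
         provider@kind)
  n <- length(corpus)
  outDim <- switch(mode, mean = 2L, mean_minmax = 6L, doc_level = 1L) *
    provider@dim
  out <- matrix(0, nrow = n, ncol = outDim)
  for (i in seq_len(n)) {
    if (mode == "doc_level") {
      out[i, ] <- provider@encode(corpus@title[i], corpus@abstract[i])
    } else {
      te <- provider@encode(tokenizer(corpus@title[i]))
      ae <- provider@encode(tokenizer(corpus@abstract[i]))
      out[i, ] <- if (mode == "mean") poolMean(te, ae)
                  else poolMeanMinMax(te, ae)
    }
  }
  rownames(out) <- corpus@pmid
  colnames(out) <- sprintf("emb_%04d", seq_len(outDim))
  out
}

#' Append a dense pooled block to a FeatureMatrix
#'
#' The sparse BoW block keeps its columns; pooled entry `k` becomes column
#' `V + k` of the combined layout.
#'
#' @param fm a [FeatureMatrix-class] (its current dense block is replaced).
#' @param pooled numeric matrix, documents x pooled dimension, rows aligned
#'   with `fm`.
#' @param providerId,poolingMode recorded on the result.
#' @return A [FeatureMatrix-class].
#' @export
concatBlocks <- function(fm, pooled, providerId = "external",
                         poolingMode = "mean") {
  stopifnot(is(fm, "FeatureMatrix"))
  if (nrow(pooled) != length(fm@pmid))
    stop("pooled block has ", nrow(pooled), " rows, expected ",
         length(fm@pmid))
  if (is.null(colnames(pooled)))
    colnames(pooled) <- sprintf("emb_%04d", seq_len(ncol(pooled)))
  new("FeatureMatrix", bow = fm@bow, dense = pooled, pmid = fm@pmid,
      vocabulary = fm@vocabulary, providerId = providerId,
      poolingMode = poolingMode)
}
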