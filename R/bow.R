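# Field-selected, n-gram-augmented bag-of-words encoding with per-document
# L1 normalisation.

.NGRAM_SEP <- "_"
.FIELD_SEP <- "="

#' Consecutive n-grams of a token sequence
#'
#' @param tokens character vector.
#' @param n n-gram order (2 or 3).
#' @return character vector of `max(0, length(tokens) - n + 1)` terms, each
#'   the `"_"`-joined window of `n` consecutive tokens.
#' @examples
#' makeNgrams(c("a", "b", "c"), 2)
#' @export
makeNgrams <- function(tokens, n) {
  n <- as.integer(n)
  if (!n %in% 2:3) stop("n must be 2 or 3")
  k <- length(tokens) - n + 1L
  if (k <= 0L) return(character())
  vapply(seq_len(k), function(i)
    paste(tokens[i:(i + n - 1L)], collapse = .NGRAM_SEP), "")
}

#' Metadata field values as namespaced single tokens
#'
#' Metadata fields are treated as single tokens without further
#' pre-processing; each value is namespaced as `"field=value"` so identical
#' strings in different fields cannot collide.
#'
#' @param corpus a [DocumentCorpus-class].
#' @param field a metadata field key from [metadataFields()] (not
#'   title/abstract).
#' @return list of character vectors, one per record.
#' @examples
#' dc <- DocumentCorpus(pmid = "1", title = "t",
#'                      publicationTypes = list("Review"))
#' fieldTerms(dc, "publication_type")
#' @export
fieldTerms <- function(corpus, field) {
  stopifnot(is(corpus, "DocumentCorpus"))
  if (!field %in% metadataFields())
    stop("unknown metadata field '", field, "'; expected one of: ",
         paste(metadataFields(), collapse = ", "))
  v <- corpusField(corpus, field)
  if (is.list(v)) {
    lapply(v, function(x)
      if (length(x)) paste0(field, .FIELD_SEP, x) else character())
  } else {
    lapply(v, function(x)
      if (nzchar(x)) paste0(field, .FIELD_SEP, x) else character())
  }
}

#' The Optimal Fields preset
#'
#' The field combination found to carry the discriminant information for PK
#' triage: title, abstract, MeSH terms and publication type.
#'
#' @return character vector of field keys.
#' @export
optimalFields <- function() {
  c("title", "abstract", "mesh_terms", "publication_type")
}

#' Per-document term lists for a corpus
#'
#' Produces the terms each document contributes to the bag-of-words
#' encoding. Title and abstract text go through the full normalisation
#' chain (tokenise, mask chemical mentions, lowercase, strip punctuation,
#' mask digits, drop stopwords, stem) and contribute unigrams plus the
#' requested higher-order n-grams (n-grams are built from the normalised
#' tokens and only from title/abstract, never from metadata). Metadata
#' fields contribute namespaced single tokens via [fieldTerms()].
#'
#' @param corpus a [DocumentCorpus-class].
#' @param fields character vector of field keys; default [optimalFields()].
#' @param ngramOrders integer vector, subset of 1:3; default 1 (unigrams).
#' @param lexicon chemical lexicon for masking; default
#'   [pkChemicalLexicon()]; empty disables masking.
#' @param stopwords stopword list, default [pkStopwords()].
#' @param tokenizer tokenizer function, default [tokenizeField()].
#' @return list of character vectors (terms per document), named by pmid.
#' @export
documentTerms <- function(corpus, fields = optimalFields(),
                          ngramOrders = 1L,
                          lexicon = pkChemicalLexicon(),
                          stopwords = pkStopwords(),
                          tokenizer = tokenizeField) {
  stopifnot(is(corpus, "DocumentCorpus"))
  ngramOrders <- sort(unique(as.integer(ngramOrders)))
  if (!all(ngramOrders %in% 1:3)) stop("ngramOrders must be drawn from 1:3")
  unknown <- setdiff(fields, names(.FIELD_KEYS))
  if (length(unknown))
    stop("unknown field(s): ", paste(unknown, collapse = ", "))
  textFields <- intersect(fields, c("title", "abstract"))
  metaFields <- intersect(fields, metadataFields())

  n <- length(corpus)
  terms <- rep(list(character()), n)
  for (f in textFields) {
    txt <- corpusField(corpus, f)
    for (i in seq_len(n)) {
      toks <- preprocessField(txt[i], lexicon = lexicon,
                              stopwords = stopwords, tokenizer = tokenizer)
      add <- character()
      if (1L %in% ngramOrders) add <- toks
      for (g in setdiff(ngramOrders, 1L))
        add <- c(add, makeNgrams(toks, g))
      terms[[i]] <- c(terms[[i]], add)
    }
  }
  for (f in metaFields) {
    ft <- fieldTerms(corpus, f)
    for (i in seq_len(n)) terms[[i]] <- c(terms[[i]], ft[[i]])
  }
  names(terms) <- corpus@pmid
  terms
}

#' Build a vocabulary from per-document term lists
#'
#' Retains terms whose document frequency (number of documents containing
#' the term at least once) is `>= minDF`, in deterministic lexicographic
#' (byte-order) column order.
#'
#' @param termsList list of character vectors, one per document (as from
#'   [documentTerms()]).
#' @param minDF minimum document frequency (>= 1); default 20, the
#'   reference pipeline default.
#' @param fieldsIncluded,ngramOrders metadata recorded on the vocabulary.
#' @return A [Vocabulary-class].
#' @export
buildVocabulary <- function(termsList, minDF = 20L,
                            fieldsIncluded = optimalFields(),
                            ngramOrders = 1L) {
  minDF <- as.integer(minDF)
  if (length(termsList) == 0L) stop("corpus must be non-empty")
  if (minDF < 1L) stop("minDF must be >= 1")
  df <- table(unlist(lapply(termsList, unique), use.names = FALSE))
  keep <- df >= minDF
  if (!any(keep))
    stop("vocabulary is empty after the min_df = ", minDF,
         " filter; lower minDF")
  terms <- names(df)[keep]
  ord <- order(terms, method = "radix")
  new("Vocabulary", terms = terms[ord],
      docFreq = as.integer(df[keep])[ord], minDF = minDF,
      fieldsIncluded = as.character(fieldsIncluded),
      ngramOrders = as.integer(ngramOrders))
}

#' Encode documents as L1-normalised bag-of-words vectors
#'
#' Entry `(d, t)` is `count(t in d) / T_d` where `T_d` is the total number
#' of in-vocabulary term occurrences in document `d`, so every row with at
#' least one counted term sums to exactly 1 (the L1 norm). Out-of-vocabulary
#' terms are ignored; a document with no in-vocabulary terms maps to the
#' zero vector. The denominator counts in-vocabulary occurrences only,
#' which is what makes the stated norm exact; set `denominator =
#' "all_terms"` for the alternative reading (divide by all terms incl.
#' filtered ones).
#'
#' @param termsList list of character vectors (terms per document).
#' @param vocab a [Vocabulary-class].
#' @param denominator `"in_vocabulary"` (default) or `"all_terms"`.
#' @return a `dgCMatrix`, documents x vocabulary terms, with `dimnames`.
#' @export
encodeBow <- function(termsList, vocab,
                      denominator = c("in_vocabulary", "all_terms")) {
  stopifnot(is(vocab, "Vocabulary"))
  denominator <- match.arg(denominator)
  nDocs <- length(termsList)
  V <- length(vocab@terms)
  ii <- list(); jj <- list(); xx <- list()
  for (d in seq_len(nDocs)) {
    terms <- termsList[[d]]
    idx <- match(terms, vocab@terms)
    inv <- idx[!is.na(idx)]
    if (length(inv) == 0L) next
    tot <- if (denominator == "in_vocabulary") length(inv) else length(terms)
    counts <- table(inv)
    ii[[d]] <- rep.int(d, length(counts))
    jj[[d]] <- as.integer(names(counts))
    xx[[d]] <- as.numeric(counts) / tot
  }
  Matrix::sparseMatrix(
    i = as.integer(unlist(ii)), j = as.integer(unlist(jj)),
    x = as.numeric(unlist(xx)), dims = c(nDocs, V),
    dimnames = list(names(termsList), vocab@terms))
}

#' Featurise a corpus end to end
#'
#' Runs [documentTerms()], [buildVocabulary()] (unless a prebuilt
#' vocabulary is supplied, e.g. at prediction time), [encodeBow()], and
#' optionally appends a pooled-embedding dense block from
#' [embedDocument()].
#'
#' @param corpus a [DocumentCorpus-class].
#' @param fields,ngramOrders,lexicon,stopwords,tokenizer passed to
#'   [documentTerms()].
#' @param minDF vocabulary threshold, passed to [buildVocabulary()].
#' @param vocab optional prebuilt [Vocabulary-class]; when supplied, minDF
#'   and vocabulary construction are skipped.
#' @param provider optional [EmbeddingProvider-class] for a dense block.
#' @param poolingMode pooling composition when `provider` is given:
#'   `"mean"`, `"mean_minmax"` or `"doc_level"`.
#' @return A [FeatureMatrix-class].
#' @export
featurizeCorpus <- function(corpus, fields = optimalFields(),
                            ngramOrders = 1L, minDF = 20L,
                            lexicon = pkChemicalLexicon(),
                            stopwords = pkStopwords(),
                            tokenizer = tokenizeField,
                            vocab = NULL, provider = NULL,
                            poolingMode = "mean") {
  termsList <- documentTerms(corpus, fields = fields,
                             ngramOrders = ngramOrders, lexicon = lexicon,
                             stopwords = stopwords, tokenizer = tokenizer)
  if (is.null(vocab))
    vocab <- buildVocabulary(termsList, minDF = minDF,
                             fieldsIncluded = fields,
                             ngramOrders = ngramOrders)
  bow <- encodeBow(termsList, vocab)
  if (is.null(provider)) {
    dense <- matrix(numeric(), nrow = length(corpus), ncol = 0L)
    providerId <- ""
    poolingMode <- ""
  } else {
    dense <- embedDocument(corpus, provider, mode = poolingMode)
    providerId <- provider@id
  }
  new("FeatureMatrix", bow = bow, dense = dense, pmid = corpus@pmid,
      vocabulary = vocab, providerId = providerId,
      poolingMode = poolingMode)
}

#' Write a vocabulary sidecar (term, index, document frequency)
#' @param vocab a [Vocabulary-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeVocabulary <- function(vocab, path) {
  stopifnot(is(vocab, "Vocabulary"))
  df <- data.frame(term = vocab@terms, index = seq_along(vocab@terms),
                   doc_freq = vocab@docFreq)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# min_df=%d fields=%s ngrams=%s", vocab@minDF,
                     paste(vocab@fieldsIncluded, collapse = ","),
                     paste(vocab@ngramOrders, collapse = ",")), con)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a vocabulary sidecar written by [writeVocabulary()]
#' @param path TSV path.
#' @return A [Vocabulary-class].
#' @export
readVocabulary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- lines[1]
  minDF <- as.integer(sub(".*min_df=([0-9]+).*", "\\1", meta))
  fields <- strsplit(sub(".*fields=([^ ]+).*", "\\1", meta), ",")[[1]]
  ngrams <- as.integer(strsplit(sub(".*ngrams=([^ ]+).*", "\\1", meta),
                                ",")[[1]])
  df <- read.delim(text = lines[-1], stringsAsFactors = FALSE)
  ord <- order(df$index)
  new("Vocabulary", terms = df$term[ord], docFreq = as.integer(df$doc_freq[ord]),
      minDF = minDF, fieldsIncluded = fields, ngramOrders = ngrams)
}
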