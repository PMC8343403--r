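# Central S4 containers. Documents are held column-wise (one character
# vector or list per field) rather than as per-record objects so that
# corpora of 10^5 records stay cheap to subset.

.LIST_FIELDS <- c("authors", "publicationTypes", "keywords",
                  "meshTerms", "chemicals", "affiliations")

#' DocumentCorpus: typed PubMed/MEDLINE records
#'
#' Holds one PubMed record per element: textual fields (`pmid`, `title`,
#' `abstract`, `journal`) as character vectors and list-valued metadata
#' (`authors`, `publicationTypes`, `keywords`, `meshTerms`, `chemicals`,
#' `affiliations`) as lists of character vectors. `pmid` values are unique
#' and non-empty and every `title` is non-empty; absent optional fields are
#' empty strings / zero-length character vectors, never `NA`.
#'
#' @slot pmid character, unique non-empty PubMed identifiers.
#' @slot title character, non-empty record titles.
#' @slot abstract character, possibly empty abstract text.
#' @slot journal character, journal name (possibly empty).
#' @slot authors,publicationTypes,keywords,meshTerms,chemicals,affiliations
#'   lists of character vectors, one element per record.
#'
#' @seealso [parsePubmedXML()], [generateCorpus()], [corpusStats()]
#' @export
setClass("DocumentCorpus",
  representation(
    pmid = "character",
    title = "character",
    abstract = "character",
    journal = "character",
    authors = "list",
    publicationTypes = "list",
    keywords = "list",
    meshTerms = "list",
    chemicals = "list",
    affiliations = "list"
  )
)

setValidity("DocumentCorpus", function(object) {
  n <- length(object@pmid)
  msgs <- character()
  for (s in c("title", "abstract", "journal", .LIST_FIELDS)) {
    if (length(slot(object, s)) != n)
      msgs <- c(msgs, sprintf("slot '%s' has length %d, expected %d",
                              s, length(slot(object, s)), n))
  }
  if (anyNA(object@pmid) || any(!nzchar(object@pmid)))
    msgs <- c(msgs, "all pmids must be non-empty")
  if (anyDuplicated(object@pmid))
    msgs <- c(msgs, "pmids must be unique within a corpus")
  if (anyNA(object@title) || any(!nzchar(object@title)))
    msgs <- c(msgs, "all titles must be non-empty")
  for (s in .LIST_FIELDS) {
    ok <- vapply(slot(object, s), is.character, logical(1))
    if (!all(ok))
      msgs <- c(msgs, sprintf("slot '%s' must contain character vectors", s))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a DocumentCorpus
#'
#' @param pmid character vector of unique non-empty identifiers.
#' @param title character vector of non-empty titles.
#' @param abstract,journal character vectors, recycled from `""` when omitted.
#' @param authors,publicationTypes,keywords,meshTerms,chemicals,affiliations
#'   lists of character vectors (one per record); default empty.
#' @return A [DocumentCorpus-class] object.
#' @examples
#' dc <- DocumentCorpus(pmid = c("1", "2"),
#'                      title = c("PK of drug X", "A review"),
#'                      abstract = c("Clearance was 5.2 L/h.", ""))
#' length(dc)
#' @export
DocumentCorpus <- function(pmid, title, abstract = character(),
                           journal = character(), authors = list(),
                           publicationTypes = list(), keywords = list(),
                           meshTerms = list(), chemicals = list(),
                           affiliations = list()) {
  n <- length(pmid)
  fill_chr <- function(x)
    if (length(x) == 0L && n > 0L) rep("", n) else unname(as.character(x))
  fill_lst <- function(x) {
    if (length(x) == 0L && n > 0L) rep(list(character()), n)
    else unname(lapply(x, function(e) unname(as.character(e))))
  }
  new("DocumentCorpus",
      pmid = unname(as.character(pmid)), title = unname(as.character(title)),
      abstract = fill_chr(abstract), journal = fill_chr(journal),
      authors = fill_lst(authors), publicationTypes = fill_lst(publicationTypes),
      keywords = fill_lst(keywords), meshTerms = fill_lst(meshTerms),
      chemicals = fill_lst(chemicals), affiliations = fill_lst(affiliations))
}

#' Vocabulary: term-to-column map for bag-of-words encoding
#'
#' Terms are stored in deterministic lexicographic (byte) order; a term's
#' column index is its position. Every retained term has document frequency
#' `>= minDF`.
#'
#' @slot terms character, sorted unique terms.
#' @slot docFreq integer, per-term document frequency (same order as terms).
#' @slot minDF integer, minimum document frequency applied.
#' @slot fieldsIncluded character, record fields the terms were drawn from.
#' @slot ngramOrders integer, n-gram orders used (subset of 1:3).
#' @seealso [buildVocabulary()], [encodeBow()]
#' @export
setClass("Vocabulary",
  representation(terms = "character", docFreq = "integer", minDF = "integer",
                 fieldsIncluded = "character", ngramOrders = "integer")
)

setValidity("Vocabulary", function(object) {
  msgs <- character()
  if (length(object@terms) != length(object@docFreq))
    msgs <- c(msgs, "terms and docFreq lengths differ")
  if (is.unsorted(object@terms) || anyDuplicated(object@terms))
    msgs <- c(msgs, "terms must be sorted and unique")
  if (length(object@docFreq) && any(object@docFreq < object@minDF))
    msgs <- c(msgs, "all document frequencies must be >= minDF")
  if (!all(object@ngramOrders %in% 1:3))
    msgs <- c(msgs, "ngramOrders must be drawn from {1,2,3}")
  if (length(msgs)) msgs else TRUE
})

#' FeatureMatrix: sparse BoW block plus optional dense embedding block
#'
#' Rows are documents (named by pmid). The bag-of-words block is an
#' L1-normalised sparse matrix over the vocabulary columns; the dense block
#' (possibly zero columns) holds pooled embedding representations.
#'
#' @slot bow dgCMatrix, documents x vocabulary, non-negative, each row with
#'   at least one counted term sums to 1.
#' @slot dense numeric matrix, documents x pooled-embedding dimensions.
#' @slot pmid character, row identifiers.
#' @slot vocabulary the [Vocabulary-class] the columns refer to.
#' @slot providerId embedding provider identifier ("" when no dense block).
#' @slot poolingMode one of "", "mean", "mean_minmax", "doc_level".
#' @seealso [featurizeCorpus()], [concatBlocks()], [combinedMatrix()]
#' @export
setClass("FeatureMatrix",
  representation(bow = "Matrix", dense = "matrix", pmid = "character",
                 vocabulary = "Vocabulary", providerId = "character",
                 poolingMode = "character")
)

setValidity("FeatureMatrix", function(object) {
  msgs <- character()
  if (nrow(object@bow) != length(object@pmid))
    msgs <- c(msgs, "bow row count must equal number of pmids")
  if (nrow(object@dense) != length(object@pmid))
    msgs <- c(msgs, "dense row count must equal number of pmids")
  if (ncol(object@bow) != length(object@vocabulary@terms))
    msgs <- c(msgs, "bow column count must equal vocabulary size")
  if (length(object@bow@x) && any(object@bow@x < 0))
    msgs <- c(msgs, "bow entries must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' EmbeddingProvider: contract for token- or document-level encoders
#'
#' A token-level provider maps the tokens of one field to a `T x d` matrix
#' (conceptually the element-wise sum of an encoder's last four hidden
#' layers); a document-level provider maps a whole record to a single
#' `d`-dimensional vector.
#'
#' @slot id provider identifier string.
#' @slot kind "token_level" or "document_level".
#' @slot dim integer embedding dimension d.
#' @slot encode function; for token_level `function(tokens)` returning a
#'   `length(tokens) x dim` matrix, for document_level
#'   `function(title, abstract)` returning a numeric vector of length `dim`.
#' @slot deterministic logical; TRUE when identical inputs always give
#'   identical outputs.
#' @seealso [hashEmbeddingProvider()], [embedDocument()]
#' @export
setClass("EmbeddingProvider",
  representation(id = "character", kind = "character", dim = "integer",
                 encode = "function", deterministic = "logical")
)

setValidity("EmbeddingProvider", function(object) {
  msgs <- character()
  if (!object@kind %in% c("token_level", "document_level"))
    msgs <- c(msgs, "kind must be 'token_level' or 'document_level'")
  if (object@dim < 1L) msgs <- c(msgs, "dim must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' BoosterConfig: gradient-boosting hyperparameters
#'
#' @slot eta learning rate (> 0), default 0.1.
#' @slot maxRounds maximum boosting iterations, default 2000.
#' @slot patience early-stopping patience in rounds (>= 1, < maxRounds),
#'   default 100.
#' @slot maxDepth maximum tree depth, default 4.
#' @slot colsampleBytree per-tree column subsample fraction in (0, 1],
#'   default 1.
#' @slot threshold decision threshold on the Relevant-class probability,
#'   default 0.5.
#' @slot seed integer RNG seed threaded into the engine.
#' @seealso [boosterConfig()], [fitBoostedClassifier()]
#' @export
setClass("BoosterConfig",
  representation(eta = "numeric", maxRounds = "integer", patience = "integer",
                 maxDepth = "integer", colsampleBytree = "numeric",
                 threshold = "numeric", seed = "integer")
)

setValidity("BoosterConfig", function(object) {
  msgs <- character()
  if (object@eta <= 0) msgs <- c(msgs, "eta must be > 0")
  if (object@colsampleBytree <= 0 || object@colsampleBytree > 1)
    msgs <- c(msgs, "colsampleBytree must lie in (0, 1]")
  if (object@patience < 1L) msgs <- c(msgs, "patience must be >= 1")
  if (object@patience >= object@maxRounds)
    msgs <- c(msgs, "patience must be < maxRounds")
  if (object@threshold < 0 || object@threshold > 1 + 1e-12)
    msgs <- c(msgs, "threshold must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a BoosterConfig
#'
#' Defaults follow the reference triage pipeline: learning rate 0.1, at most
#' 2000 boosting rounds with early stopping after 100 rounds without
#' improvement of the dev-set F1, tree depth 4, no column subsampling, and
#' a 0.5 decision threshold. All other engine hyperparameters stay at the
#' engine's documented defaults.
#'
#' @param eta,maxRounds,patience,maxDepth,colsampleBytree,threshold,seed
#'   see [BoosterConfig-class].
#' @return A [BoosterConfig-class] object.
#' @export
boosterConfig <- function(eta = 0.1, maxRounds = 2000L, patience = 100L,
                          maxDepth = 4L, colsampleBytree = 1,
                          threshold = 0.5, seed = 1L) {
  new("BoosterConfig", eta = eta, maxRounds = as.integer(maxRounds),
      patience = as.integer(patience), maxDepth = as.integer(maxDepth),
      colsampleBytree = colsampleBytree, threshold = threshold,
      seed = as.integer(seed))
}

#' TrainedPipeline: fitted boosted ensemble plus its feature layout
#'
#' The ensemble is a weighted sum of decision trees truncated at the
#' boosting round with the best dev-set F1; each learner's weight is
#' absorbed into its fitted leaf values, scaled by the learning rate.
#'
#' @slot booster the fitted boosting engine handle.
#' @slot bestIteration integer, number of learners retained.
#' @slot threshold decision threshold on the Relevant probability.
#' @slot featureNames character, training column layout.
#' @slot config the [BoosterConfig-class] used.
#' @slot devHistory numeric, dev-set F1 recorded at each boosting round.
#' @seealso [fitBoostedClassifier()], [predict,TrainedPipeline-method]
#' @export
setClass("TrainedPipeline",
  representation(booster = "ANY", bestIteration = "integer",
                 threshold = "numeric", featureNames = "character",
                 config = "BoosterConfig", devHistory = "numeric")
)

#' BootstrapSummary: metric distribution over bootstrap iterations
#'
#' @slot samples data.frame with columns iteration, precision, recall, f1
#'   (one row per iteration).
#' @slot summary data.frame with columns metric, median, lower, upper
#'   (95% CI as empirical 2.5th/97.5th percentiles).
#' @slot f1IQV interquartile range of the F1 samples, percent scale.
#' @slot nIterations integer iteration count.
#' @slot seed master seed used.
#' @seealso [bootstrapCompare()], [summarizeMetrics()]
#' @export
setClass("BootstrapSummary",
  representation(samples = "data.frame", summary = "data.frame",
                 f1IQV = "numeric", nIterations = "integer", seed = "integer")
)

setValidity("BootstrapSummary", function(object) {
  msgs <- character()
  if (nrow(object@samples) != object@nIterations)
    msgs <- c(msgs, "samples must have one row per iteration")
  s <- object@summary
  if (nrow(s) && any(s$lower > s$median + 1e-12 | s$median > s$upper + 1e-12))
    msgs <- c(msgs, "summary must satisfy lower <= median <= upper")
  if (length(msgs)) msgs else TRUE
})

#' AgreementResult: chance-corrected inter-annotator agreement
#'
#' Cohen's kappa K = (p_o - p_e) / (1 - p_e), where p_o is the observed
#' agreement and p_e the agreement expected by chance from the annotators'
#' marginal label frequencies.
#'
#' @slot po observed agreement in \[0, 1\].
#' @slot pe chance agreement in \[0, 1).
#' @slot kappa K in \[-1, 1\].
#' @seealso [cohenKappa()]
#' @export
setClass("AgreementResult",
  representation(po = "numeric", pe = "numeric", kappa = "numeric")
)
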