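# Synthetic labelled corpora with the statistical structure the triage
# classifier exploits: label-correlated PK-parameter-like signal tokens in
# the abstract (or title), a label-correlated "Review" publication type,
# Zipf-distributed background text, and partially missing abstracts.

#' GeneratorConfig: synthetic corpus parameters
#'
#' Defaults emulate the labelled PK corpus: ~20% Relevant prevalence and
#' ~13% missing abstracts; Relevant documents carry PK-parameter-like
#' signal terms with high probability and Not Relevant documents rarely;
#' Not Relevant documents are often typed "Review".
#'
#' @slot nDocs number of documents (>= 10).
#' @slot prevalence Relevant fraction, default 0.2; label counts are exact
#'   (`round(nDocs * prevalence)`), not sampled.
#' @slot signalTokens PK-parameter-like terms (multi-word terms included so
#'   the n-gram path is exercised).
#' @slot pSignalRelevant,pSignalIrrelevant per-signal-token injection
#'   probability in Relevant / Not Relevant documents (defaults 0.9 /
#'   0.05).
#' @slot backgroundVocabSize,zipfExponent background vocabulary size and
#'   Zipf rank exponent for filler text.
#' @slot pAbstractMissing probability an abstract is dropped, default 0.13.
#' @slot pReviewNotRelevant,pReviewRelevant probability of publication type
#'   "Review" per class (defaults 0.5 / 0.02).
#' @slot signalField where signal tokens go: "both" (default: title and
#'   abstract carry the label signal), "abstract" or "title".
#' @slot seed mandatory integer seed.
#' @seealso [generatorConfig()], [generateCorpus()]
#' @export
setClass("GeneratorConfig",
  representation(nDocs = "integer", prevalence = "numeric",
                 signalTokens = "character", pSignalRelevant = "numeric",
                 pSignalIrrelevant = "numeric",
                 backgroundVocabSize = "integer", zipfExponent = "numeric",
                 pAbstractMissing = "numeric",
                 pReviewNotRelevant = "numeric", pReviewRelevant = "numeric",
                 signalField = "character", seed = "integer")
)

setValidity("GeneratorConfig", function(object) {
  msgs <- character()
  probs <- c(object@prevalence, object@pSignalRelevant,
             object@pSignalIrrelevant, object@pAbstractMissing,
             object@pReviewNotRelevant, object@pReviewRelevant)
  if (any(probs < 0 | probs > 1)) msgs <- c(msgs, "probabilities must lie in [0,1]")
  if (object@nDocs < 10L) msgs <- c(msgs, "nDocs must be >= 10")
  if (!object@signalField %in% c("abstract", "title", "both"))
    msgs <- c(msgs, "signalField must be abstract, title or both")
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "seed is mandatory")
  if (length(msgs)) msgs else TRUE
})

.DEFAULT_SIGNAL <- c("clearance", "half-life", "bioavailability",
                     "volume of distribution", "area under the curve",
                     "elimination rate constant", "cmax", "auc")

#' Construct a GeneratorConfig
#'
#' @param nDocs number of documents.
#' @param seed mandatory integer seed.
#' @param prevalence,signalTokens,pSignalRelevant,pSignalIrrelevant see
#'   [GeneratorConfig-class].
#' @param backgroundVocabSize,zipfExponent,pAbstractMissing see
#'   [GeneratorConfig-class].
#' @param pReviewNotRelevant,pReviewRelevant,signalField see
#'   [GeneratorConfig-class].
#' @return A [GeneratorConfig-class].
#' @export
generatorConfig <- function(nDocs, seed, prevalence = 0.2,
                            signalTokens = .DEFAULT_SIGNAL,
                            pSignalRelevant = 0.9,
                            pSignalIrrelevant = 0.05,
                            backgroundVocabSize = 500L,
                            zipfExponent = 1.05,
                            pAbstractMissing = 0.13,
                            pReviewNotRelevant = 0.5,
                            pReviewRelevant = 0.02,
                            signalField = "both") {
  if (missing(seed)) stop("seed is mandatory")
  new("GeneratorConfig", nDocs = as.integer(nDocs),
      prevalence = prevalence, signalTokens = signalTokens,
      pSignalRelevant = pSignalRelevant,
      pSignalIrrelevant = pSignalIrrelevant,
      backgroundVocabSize = as.integer(backgroundVocabSize),
      zipfExponent = zipfExponent, pAbstractMissing = pAbstractMissing,
      pReviewNotRelevant = pReviewNotRelevant,
      pReviewRelevant = pReviewRelevant, signalField = signalField,
      seed = as.integer(seed))
}

.JOURNALS <- c("Journal of Pharmacokinetics", "Clinical Drug Research",
               "Therapeutic Monitoring Letters", "Applied Pharmacology",
               "Drug Metabolism Quarterly")
.MESH_POOL <- sprintf("Descriptor%02d", 1:30)

#' Generate a labelled synthetic corpus
#'
#' Labels are assigned by exact count (`round(nDocs * prevalence)` Relevant)
#' and shuffled; Relevant documents receive each signal token with
#' probability `pSignalRelevant` (Not Relevant with `pSignalIrrelevant`) in
#' the configured field; Not Relevant documents carry publication type
#' "Review" at the configured rate; abstracts are dropped at
#' `pAbstractMissing` (after signal injection, so a missing abstract loses
#' its signal, as with real records). Fully deterministic given the seed
#' and leaves the caller's RNG state untouched.
#'
#' @param config a [GeneratorConfig-class].
#' @return list with `corpus` (a [DocumentCorpus-class]) and `labels`
#'   (data.frame pmid/label).
#' @examples
#' gen <- generateCorpus(generatorConfig(nDocs = 50, seed = 1))
#' table(gen$labels$label)
#' @export
generateCorpus <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config@seed)

  n <- config@nDocs
  nRel <- round(n * config@prevalence)
  labels <- rep(c("Relevant", "NotRelevant"), c(nRel, n - nRel))
  labels <- sample(labels)
  rel <- labels == "Relevant"

  V <- config@backgroundVocabSize
  bg <- sprintf("pharmword%03d", seq_len(V))
  probs <- seq_len(V)^(-config@zipfExponent)
  probs <- probs / sum(probs)
  drawBg <- function(k) paste(sample(bg, k, replace = TRUE, prob = probs),
                              collapse = " ")
  injectSignal <- function(text, p) {
    for (tok in config@signalTokens) {
      if (stats::runif(1) < p) {
        words <- strsplit(text, " ", fixed = TRUE)[[1]]
        pos <- sample.int(length(words) + 1L, 1L) - 1L
        words <- append(words, tok, after = pos)
        text <- paste(words, collapse = " ")
      }
    }
    text
  }

  pmids <- as.character(seq_len(n) + 10000000L)
  titles <- character(n)
  abstracts <- character(n)
  pubTypes <- vector("list", n)
  meshes <- vector("list", n)
  chems <- vector("list", n)
  authors <- vector("list", n)
  affils <- vector("list", n)
  lexicon <- pkChemicalLexicon()
  for (i in seq_len(n)) {
    p <- if (rel[i]) config@pSignalRelevant else config@pSignalIrrelevant
    titles[i] <- paste("Study of", drawBg(sample(5:9, 1)))
    if (config@signalField %in% c("title", "both"))
      titles[i] <- injectSignal(titles[i], p)
    abstracts[i] <- drawBg(sample(40:80, 1))
    if (config@signalField %in% c("abstract", "both"))
      abstracts[i] <- injectSignal(abstracts[i], p)
    if (stats::runif(1) < 0.3) {
      drug <- sample(lexicon, 1)
      chems[[i]] <- drug
      abstracts[i] <- paste(abstracts[i], drug)
    } else chems[[i]] <- character()
    if (stats::runif(1) < config@pAbstractMissing) abstracts[i] <- ""
    pReview <- if (rel[i]) config@pReviewRelevant else config@pReviewNotRelevant
    pubTypes[[i]] <- if (stats::runif(1) < pReview) "Review"
                     else "Journal Article"
    meshes[[i]] <- sample(.MESH_POOL, sample(2:5, 1))
    authors[[i]] <- sprintf("Author %03d", sample.int(300, sample(1:4, 1)))
    affils[[i]] <- if (stats::runif(1) < 0.8)
      sprintf("Institute %02d", sample.int(40, 1)) else character()
  }
  corpus <- DocumentCorpus(
    pmid = pmids, title = titles, abstract = abstracts,
    journal = sample(.JOURNALS, n, replace = TRUE),
    authors = authors, publicationTypes = pubTypes,
    keywords = rep(list(character()), n), meshTerms = meshes,
    chemicals = chems, affiliations = affils)
  list(corpus = corpus,
       labels = data.frame(pmid = pmids,
                           label = factor(labels, levels = labelLevels()),
                           stringsAsFactors = FALSE))
}
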