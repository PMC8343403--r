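#' @describeIn DocumentCorpus-class number of records.
#' @param x a DocumentCorpus.
#' @export
setMethod("length", "DocumentCorpus", function(x) length(x@pmid))

#' @describeIn DocumentCorpus-class subset records by index, logical mask or
#'   pmid.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @aliases [,DocumentCorpus-method
#' @export
setMethod("[", "DocumentCorpus", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(i, x@pmid)
    if (anyNA(idx)) stop("unknown pmid(s): ", paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  new("DocumentCorpus",
      pmid = x@pmid[i], title = x@title[i], abstract = x@abstract[i],
      journal = x@journal[i], authors = x@authors[i],
      publicationTypes = x@publicationTypes[i], keywords = x@keywords[i],
      meshTerms = x@meshTerms[i], chemicals = x@chemicals[i],
      affiliations = x@affiliations[i])
})

#' @export
setMethod("show", "DocumentCorpus", function(object) {
  n <- length(object)
  cat(sprintf("DocumentCorpus with %d record%s\n", n, if (n == 1) "" else "s"))
  if (n > 0) {
    k <- min(n, 3L)
    for (i in seq_len(k))
      cat(sprintf("  [%s] %s\n", object@pmid[i],
                  substr(object@title[i], 1, 60)))
    if (n > k) cat(sprintf("  ... and %d more\n", n - k))
    avail <- 100 * mean(nzchar(object@abstract))
    cat(sprintf("  abstract available: %.1f%%\n", avail))
  }
  invisible(object)
})

#' PubMed identifiers of a corpus
#' @param x a [DocumentCorpus-class].
#' @return character vector of pmids.
#' @export
pmid <- function(x) {
  stopifnot(is(x, "DocumentCorpus"))
  x@pmid
}

# canonical snake_case field keys used in external interfaces and configs
.FIELD_KEYS <- c(title = "title", abstract = "abstract", journal = "journal",
                 authors = "authors", publication_type = "publicationTypes",
                 keywords = "keywords", mesh_terms = "meshTerms",
                 chemicals = "chemicals", affiliations = "affiliations")

#' Extract one field from a corpus
#'
#' @param x a [DocumentCorpus-class].
#' @param field a canonical field key: one of `r paste0('\x60',
#'   names(pkTriage:::.FIELD_KEYS), '\x60', collapse = ", ")`.
#' @return character vector (textual fields) or list of character vectors
#'   (metadata fields), one element per record.
#' @export
corpusField <- function(x, field) {
  stopifnot(is(x, "DocumentCorpus"))
  if (!field %in% names(.FIELD_KEYS))
    stop("unknown field '", field, "'; expected one of: ",
         paste(names(.FIELD_KEYS), collapse = ", "))
  slot(x, .FIELD_KEYS[[field]])
}

#' Fields available as metadata terms (everything except title/abstract)
#' @return character vector of canonical field keys.
#' @export
metadataFields <- function() {
  setdiff(names(.FIELD_KEYS), c("title", "abstract"))
}

#' @describeIn Vocabulary-class number of retained terms.
#' @param x a Vocabulary.
#' @export
setMethod("length", "Vocabulary", function(x) length(x@terms))

#' @export
setMethod("show", "Vocabulary", function(object) {
  cat(sprintf("Vocabulary: %d terms (min_df = %d)\n",
              length(object@terms), object@minDF))
  cat("  fields:", paste(object@fieldsIncluded, collapse = ", "), "\n")
  cat("  n-gram orders:", paste(object@ngramOrders, collapse = ", "), "\n")
  if (length(object@terms))
    cat("  first terms:", paste(head(object@terms, 5), collapse = ", "), "\n")
  invisible(object)
})

#' Terms of a vocabulary, in column order
#' @param vocab a [Vocabulary-class].
#' @return character vector; position = column index.
#' @export
vocabTerms <- function(vocab) {
  stopifnot(is(vocab, "Vocabulary"))
  vocab@terms
}

#' @describeIn FeatureMatrix-class dimensions (documents x total columns).
#' @param x a FeatureMatrix.
#' @export
setMethod("dim", "FeatureMatrix", function(x)
  c(nrow(x@bow), ncol(x@bow) + ncol(x@dense)))

#' @export
setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d documents, %d BoW + %d dense columns\n",
              nrow(object@bow), ncol(object@bow), ncol(object@dense)))
  if (nzchar(object@providerId))
    cat(sprintf("  embeddings: %s (%s pooling)\n",
                object@providerId, object@poolingMode))
  invisible(object)
})

#' Combined numeric design matrix of a FeatureMatrix
#'
#' Concatenates the sparse BoW block and the dense pooled block; column
#' `V + k` is pooled entry `k` for a vocabulary of size `V`.
#'
#' @param fm a [FeatureMatrix-class].
#' @return a `dgCMatrix` with named columns.
#' @export
combinedMatrix <- function(fm) {
  stopifnot(is(fm, "FeatureMatrix"))
  bow <- fm@bow
  colnames(bow) <- fm@vocabulary@terms
  if (ncol(fm@dense) == 0L) return(methods::as(bow, "CsparseMatrix"))
  dn <- fm@dense
  if (is.null(colnames(dn)))
    colnames(dn) <- sprintf("emb_%04d", seq_len(ncol(dn)))
  out <- cbind(methods::as(bow, "CsparseMatrix"),
               methods::as(Matrix::Matrix(dn, sparse = TRUE), "CsparseMatrix"))
  methods::as(out, "CsparseMatrix")
}

#' @export
setMethod("show", "EmbeddingProvider", function(object) {
  cat(sprintf("EmbeddingProvider '%s': %s, d = %d%s\n", object@id,
              object@kind, object@dim,
              if (object@deterministic) " (deterministic)" else ""))
  invisible(object)
})

#' @export
setMethod("show", "BoosterConfig", function(object) {
  cat(sprintf(paste0("BoosterConfig: eta = %g, max rounds = %d, patience = %d,",
                     " depth = %d, colsample = %g, threshold = %g, seed = %d\n"),
              object@eta, object@maxRounds, object@patience, object@maxDepth,
              object@colsampleBytree, object@threshold, object@seed))
  invisible(object)
})

#' @export
setMethod("show", "TrainedPipeline", function(object) {
  cat(sprintf("TrainedPipeline: %d learners (best iteration), %d features, threshold %g\n",
              object@bestIteration, length(object@featureNames),
              object@threshold))
  invisible(object)
})

#' @export
setMethod("show", "BootstrapSummary", function(object) {
  cat(sprintf("BootstrapSummary over %d iterations (seed %d)\n",
              object@nIterations, object@seed))
  s <- object@summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s median %.3f (95%% CI %.3f, %.3f)\n",
                s$metric[i], s$median[i], s$lower[i], s$upper[i]))
  cat(sprintf("  F1 IQV: %.1f\n", object@f1IQV))
  invisible(object)
})

#' @export
setMethod("show", "AgreementResult", function(object) {
  cat(sprintf("Cohen's kappa: K = %.4f (observed %.4f, chance %.4f)\n",
              object@kappa, object@po, object@pe))
  invisible(object)
})
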