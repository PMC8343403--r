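# Token normalisation chain for title/abstract text: rule-based
# tokenisation, chemical-mention masking, lowercasing, punctuation
# stripping, digit masking, stopword removal, Porter stemming.

.MASK_CHEM <- "@CHEM"
.MASK_DIGIT <- "##"

#' Mask token constants
#' @return named character vector: `chemical` mask (`@CHEM`) and `digit`
#'   mask (`##`).
#' @export
maskTokens <- function() c(chemical = .MASK_CHEM, digit = .MASK_DIGIT)

#' Rule-based tokeniser for scientific text
#'
#' Splits on whitespace and punctuation boundaries while keeping decimal
#' numbers (`5.2`) and hyphenated terms (`half-life`) whole; every
#' punctuation character that is not part of such a unit becomes its own
#' token. Concatenating the tokens recovers every non-whitespace character
#' of the input. The tokeniser is the default of a pluggable contract: any
#' `function(text) -> character` may be supplied wherever a tokenizer
#' argument is accepted.
#'
#' @param text a single character string (may be empty or NA).
#' @return character vector of tokens; empty input gives `character(0)`.
#' @examples
#' tokenizeField("Clearance was 5.2 L/h.")
#' tokenizeField("half-life")
#' @export
tokenizeField <- function(text) {
  if (length(text) != 1L) stop("tokenizeField() expects a single string")
  if (is.na(text) || !nzchar(text)) return(character())
  pat <- "(*UCP)\\d+\\.\\d+|[[:alnum:]]+(?:['’-][[:alnum:]]+)*|[^[:space:]]"
  m <- gregexpr(pat, text, perl = TRUE)
  regmatches(text, m)[[1]]
}

#' Detect chemical mentions with a dictionary masker
#'
#' Scans a token sequence for (possibly multi-token) chemical names from a
#' lexicon, case-insensitively, preferring the longest match at each
#' position. This is the deterministic default behind a pluggable
#' entity-masker contract (an external NER adapter may produce the same
#' span format).
#'
#' @param tokens character vector of tokens.
#' @param lexicon character vector of chemical names; multi-word names are
#'   split on whitespace and matched as consecutive tokens.
#' @return integer matrix with columns `start`, `end` (1-based token
#'   indices, inclusive); zero rows when nothing matches.
#' @examples
#' detectChemicals(c("midazolam", "clearance"), c("midazolam"))
#' @export
detectChemicals <- function(tokens, lexicon) {
  spans <- matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (length(tokens) == 0L || length(lexicon) == 0L) return(spans)
  low <- tolower(tokens)
  entries <- strsplit(tolower(lexicon), "[[:space:]]+")
  entries <- entries[lengths(entries) > 0L]
  if (length(entries) == 0L) return(spans)
  entries <- entries[order(-lengths(entries))]  # longest first
  i <- 1L
  out <- list()
  while (i <= length(low)) {
    matched <- 0L
    for (e in entries) {
      k <- length(e)
      if (i + k - 1L <= length(low) &&
          identical(low[i:(i + k - 1L)], e)) {
        matched <- k
        break
      }
    }
    if (matched > 0L) {
      out[[length(out) + 1L]] <- c(i, i + matched - 1L)
      i <- i + matched
    } else i <- i + 1L
  }
  if (length(out))
    spans <- matrix(unlist(out), ncol = 2L, byrow = TRUE,
                    dimnames = list(NULL, c("start", "end")))
  spans
}

#' Replace entity spans by a single mask token
#'
#' Every span collapses to exactly one mask token (so a two-token mention
#' shortens the sequence by one); tokens outside spans are unchanged.
#' Masking chemical mentions with one shared token prevents the classifier
#' from keying on specific compound names.
#'
#' @param tokens character vector.
#' @param spans integer matrix with columns `start`, `end` (1-based,
#'   inclusive) as from [detectChemicals()].
#' @param mask mask token, default `"@CHEM"`.
#' @return character vector with spans replaced.
#' @export
maskEntities <- function(tokens, spans, mask = .MASK_CHEM) {
  if (is.null(spans) || nrow(spans) == 0L) return(tokens)
  spans <- spans[order(spans[, 1L]), , drop = FALSE]
  if (any(spans[, 2L] < spans[, 1L]))
    stop("invalid span: end < start")
  if (any(spans < 1L) || any(spans > length(tokens)))
    stop("span out of bounds for a sequence of length ", length(tokens))
  if (nrow(spans) > 1L &&
      any(spans[-1L, 1L] <= spans[-nrow(spans), 2L]))
    stop("overlapping spans")
  out <- character()
  pos <- 1L
  for (r in seq_len(nrow(spans))) {
    s <- spans[r, 1L]; e <- spans[r, 2L]
    if (pos < s) out <- c(out, tokens[pos:(s - 1L)])
    out <- c(out, mask)
    pos <- e + 1L
  }
  if (pos <= length(tokens)) out <- c(out, tokens[pos:length(tokens)])
  out
}

#' Frozen English stopword list
#'
#' The standard English stopword list shipped with the package (derived
#' from the usual NLP-toolkit list), lowercased and with punctuation
#' removed so it matches tokens after the punctuation-stripping stage.
#' Frozen in `inst/extdata/stopwords_en.txt` for reproducibility.
#'
#' @return character vector of stopwords.
#' @export
pkStopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "pkTriage")
  if (!nzchar(path)) stop("stopword list not found in installed package")
  readLines(path, encoding = "UTF-8")
}

#' Normalise a token sequence for bag-of-words encoding
#'
#' Applies, in order: lowercasing; removal of punctuation characters inside
#' tokens (tokens reduced to nothing are dropped); replacement of all-digit
#' tokens by the digit mask `##` (so after punctuation stripping `3.5` ->
#' `35` -> `##`, the most aggressive consistent reading — set
#' `maskDecimals = FALSE` to exempt tokens that were decimals); stopword
#' removal; Porter stemming. Mask tokens (`@CHEM`, `##`) are exempt from
#' every transformation.
#'
#' @param tokens character vector (typically from [tokenizeField()],
#'   possibly after [maskEntities()]).
#' @param stopwords character vector, default [pkStopwords()].
#' @param stem apply the Porter stemmer (default TRUE).
#' @param maskDecimals treat decimal-number tokens like all-digit tokens
#'   (default TRUE).
#' @return character vector of normalised tokens (possibly shorter).
#' @examples
#' normalizeTokens(c("Clearance", "was", "5.2", "L", "/", "h", "."))
#' @export
normalizeTokens <- function(tokens, stopwords = pkStopwords(), stem = TRUE,
                            maskDecimals = TRUE) {
  if (length(tokens) == 0L) return(character())
  protected <- tokens %in% c(.MASK_CHEM, .MASK_DIGIT)
  out <- tokens
  wasDecimal <- grepl("^[0-9]+\\.[0-9]+$", out)
  out[!protected] <- tolower(out[!protected])
  out[!protected] <- gsub("(*UCP)[[:punct:]]", "", out[!protected], perl = TRUE)
  keep <- protected | nzchar(out)
  out <- out[keep]; protected <- protected[keep]; wasDecimal <- wasDecimal[keep]
  digit <- !protected & grepl("^[0-9]+$", out)
  if (!maskDecimals) digit <- digit & !wasDecimal
  out[digit] <- .MASK_DIGIT
  protected <- protected | digit
  keep <- protected | !(out %in% stopwords)
  out <- out[keep]; protected <- protected[keep]
  if (stem) out[!protected] <- porterStem(out[!protected])
  out
}

#' Full preprocessing for one text field
#'
#' Convenience composition: tokenise, mask dictionary chemicals, normalise.
#'
#' @param text single string.
#' @param lexicon chemical lexicon (character); empty disables masking.
#' @param stopwords,stem,maskDecimals passed to [normalizeTokens()].
#' @param tokenizer tokenizer function, default [tokenizeField()].
#' @return character vector of normalised tokens.
#' @export
preprocessField <- function(text, lexicon = character(),
                            stopwords = pkStopwords(), stem = TRUE,
                            maskDecimals = TRUE, tokenizer = tokenizeField) {
  toks <- tokenizer(text)
  if (length(lexicon))
    toks <- maskEntities(toks, detectChemicals(toks, lexicon))
  normalizeTokens(toks, stopwords = stopwords, stem = stem,
                  maskDecimals = maskDecimals)
}

#' Default chemical-name lexicon
#'
#' Small dictionary of common drug names shipped for the deterministic
#' dictionary masker; real deployments would plug in an NER adapter.
#'
#' @return character vector of chemical names (may be multi-word).
#' @export
pkChemicalLexicon <- function() {
  path <- system.file("extdata", "chemical_lexicon.txt", package = "pkTriage")
  if (!nzchar(path)) stop("chemical lexicon not found in installed package")
  readLines(path, encoding = "UTF-8")
}
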