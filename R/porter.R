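# Porter's suffix-stripping stemmer (the original 1980 algorithm).
# Implemented here because no stemming library is part of the package's
# dependency set; behaviour follows the published algorithm definition,
# including its treatment of y (a vowel only when preceded by a consonant)
# and the longest-match rule within each step.

# consonant/vowel typing of a lowercase word: TRUE = consonant
.pcons <- function(chars) {
  n <- length(chars)
  cons <- !(chars %in% c("a", "e", "i", "o", "u"))
  for (i in seq_len(n)) {
    if (chars[i] == "y")
      cons[i] <- if (i == 1L) TRUE else !cons[i - 1L]
  }
  cons
}

# the measure m: number of VC sequences in [C](VC)^m[V]
.pmeasure <- function(chars) {
  if (length(chars) == 0L) return(0L)
  runs <- rle(.pcons(chars))$values
  # count V runs that are followed by a C run
  m <- 0L
  for (i in seq_along(runs)) {
    if (!runs[i] && i < length(runs) && runs[i + 1L]) m <- m + 1L
  }
  m
}

.phasVowel <- function(chars) {
  length(chars) > 0L && any(!.pcons(chars))
}

# *d: ends with a double consonant
.pdoubleC <- function(chars) {
  n <- length(chars)
  if (n < 2L) return(FALSE)
  cons <- .pcons(chars)
  chars[n] == chars[n - 1L] && cons[n] && cons[n - 1L]
}

# *o: ends cvc where the final consonant is not w, x or y
.pcvc <- function(chars) {
  n <- length(chars)
  if (n < 3L) return(FALSE)
  cons <- .pcons(chars)
  cons[n] && !cons[n - 1L] && cons[n - 2L] &&
    !(chars[n] %in% c("w", "x", "y"))
}

.pends <- function(chars, suffix) {
  s <- strsplit(suffix, "")[[1]]
  n <- length(chars)
  k <- length(s)
  n >= k && all(chars[(n - k + 1L):n] == s)
}

.pdropLast <- function(chars, k) chars[seq_len(length(chars) - k)]

# replace suffix `suf` by `rep` when the stem measure condition holds;
# returns NULL when the suffix does not match (so shorter suffixes may be
# tried) and the unchanged word when it matches but the condition fails
# (longest-match semantics: matching a suffix consumes the step).
.ptryRule <- function(chars, suf, rep, minM) {
  if (!.pends(chars, suf)) return(NULL)
  stem <- .pdropLast(chars, nchar(suf))
  if (.pmeasure(stem) > minM)
    c(stem, if (nzchar(rep)) strsplit(rep, "")[[1]])
  else chars
}

.pstep2345 <- function(chars, rules, minM) {
  for (i in seq_len(nrow(rules))) {
    res <- .ptryRule(chars, rules$suf[i], rules$rep[i], minM)
    if (!is.null(res)) return(res)
  }
  chars
}

.P2 <- data.frame(
  suf = c("ational", "ization", "iveness", "fulness", "ousness", "tional",
          "biliti", "enci", "anci", "izer", "abli", "alli", "entli",
          "ousli", "ation", "alism", "aliti", "iviti", "ator", "eli"),
  rep = c("ate", "ize", "ive", "ful", "ous", "tion",
          "ble", "ence", "ance", "ize", "able", "al", "ent",
          "ous", "ate", "al", "al", "ive", "ate", "e"),
  stringsAsFactors = FALSE)
.P2 <- .P2[order(-nchar(.P2$suf)), ]

.P3 <- data.frame(
  suf = c("icate", "ative", "alize", "iciti", "ical", "ful", "ness"),
  rep = c("ic", "", "al", "ic", "ic", "", ""),
  stringsAsFactors = FALSE)
.P3 <- .P3[order(-nchar(.P3$suf)), ]

.P4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
         "ism", "ate", "iti", "ous", "ive", "ize", "ion", "al", "er",
         "ic", "ou")

.porterOne <- function(word) {
  if (nchar(word) <= 2L) return(word)
  ch <- strsplit(word, "")[[1]]

  # Step 1a: plurals
  if (.pends(ch, "sses")) ch <- .pdropLast(ch, 2L)
  else if (.pends(ch, "ies")) ch <- c(.pdropLast(ch, 3L), "i")
  else if (!.pends(ch, "ss") && .pends(ch, "s")) ch <- .pdropLast(ch, 1L)

  # Step 1b: -eed / -ed / -ing
  fired <- FALSE
  if (.pends(ch, "eed")) {
    if (.pmeasure(.pdropLast(ch, 3L)) > 0L) ch <- .pdropLast(ch, 1L)
  } else if (.pends(ch, "ed") && .phasVowel(.pdropLast(ch, 2L))) {
    ch <- .pdropLast(ch, 2L); fired <- TRUE
  } else if (.pends(ch, "ing") && .phasVowel(.pdropLast(ch, 3L))) {
    ch <- .pdropLast(ch, 3L); fired <- TRUE
  }
  if (fired) {
    if (.pends(ch, "at") || .pends(ch, "bl") || .pends(ch, "iz")) {
      ch <- c(ch, "e")
    } else if (.pdoubleC(ch) && !ch[length(ch)] %in% c("l", "s", "z")) {
      ch <- .pdropLast(ch, 1L)
    } else if (.pmeasure(ch) == 1L && .pcvc(ch)) {
      ch <- c(ch, "e")
    }
  }

  # Step 1c: terminal y -> i when the stem has a vowel
  if (.pends(ch, "y") && .phasVowel(.pdropLast(ch, 1L)))
    ch <- c(.pdropLast(ch, 1L), "i")

  # Steps 2 and 3: derivational suffix mappings (m > 0)
  ch <- .pstep2345(ch, .P2, 0L)
  ch <- .pstep2345(ch, .P3, 0L)

  # Step 4: strip residual suffixes (m > 1); -ion only after s or t
  for (suf in .P4) {
    if (!.pends(ch, suf)) next
    stem <- .pdropLast(ch, nchar(suf))
    if (suf == "ion" &&
        !(length(stem) && stem[length(stem)] %in% c("s", "t"))) break
    if (.pmeasure(stem) > 1L) ch <- stem
    break
  }

  # Step 5a: drop terminal e
  if (.pends(ch, "e")) {
    stem <- .pdropLast(ch, 1L)
    m <- .pmeasure(stem)
    if (m > 1L || (m == 1L && !.pcvc(stem))) ch <- stem
  }
  # Step 5b: -ll -> -l when m > 1
  if (.pmeasure(ch) > 1L && .pdoubleC(ch) && ch[length(ch)] == "l")
    ch <- .pdropLast(ch, 1L)

  paste(ch, collapse = "")
}

#' Porter stemmer
#'
#' Reduces English words to their stems with the classic Porter
#' suffix-stripping algorithm (five rule steps applied in sequence with
#' longest-match suffix selection). Input is expected lowercase; words of
#' one or two letters are returned unchanged.
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems, same length.
#' @examples
#' porterStem(c("clearance", "pharmacokinetics", "estimated"))
#' @export
porterStem <- function(words) {
  vapply(words, .porterOne, "", USE.NAMES = FALSE)
}
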