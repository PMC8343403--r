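# MEDLINE/PubMed XML ingestion and label-table I/O.

#' Parse PubMed/MEDLINE XML into a DocumentCorpus
#'
#' Reads MEDLINE citation XML (baseline or updatefile dialect; the citations
#' may sit under `PubmedArticleSet/PubmedArticle` or directly under a
#' `MedlineCitationSet` wrapper) into a typed corpus. Structured abstracts
#' (multiple `AbstractText` sections) are concatenated in document order
#' separated by single spaces. MeSH headings keep descriptor names only;
#' qualifiers are dropped. Citations without a PMID are skipped with a
#' warning reporting the skip count. When several files (or one file) carry
#' the same PMID, the last record wins, as with PubMed update files.
#'
#' @param paths character vector of `.xml` or `.xml.gz` file paths, read in
#'   order.
#' @return A [DocumentCorpus-class]. Absent optional fields become empty
#'   strings / empty character vectors.
#' @examples
#' xml <- system.file("extdata", "mini_medline.xml", package = "pkTriage")
#' parsePubmedXML(xml)
#' @export
parsePubmedXML <- function(paths) {
  recs <- list()
  skipped <- 0L
  for (path in paths) {
    if (!file.exists(path)) stop("no such file: ", path)
    doc <- xml2::read_xml(path)
    cites <- xml2::xml_find_all(doc, "//MedlineCitation")
    for (cite in cites) {
      pm <- xml2::xml_text(xml2::xml_find_first(cite, "./PMID"))
      if (is.na(pm) || !nzchar(pm)) {
        skipped <- skipped + 1L
        next
      }
      if (!is.null(recs[[pm]]))
        message("duplicate PMID ", pm, ": keeping the last record seen")
      recs[[pm]] <- .parseCitation(cite, pm)
    }
  }
  if (skipped > 0L)
    warning(sprintf("skipped %d citation(s) lacking a PMID", skipped))
  if (length(recs) == 0L)
    return(DocumentCorpus(pmid = character(), title = character()))
  DocumentCorpus(
    pmid = vapply(recs, `[[`, "", "pmid"),
    title = vapply(recs, `[[`, "", "title"),
    abstract = vapply(recs, `[[`, "", "abstract"),
    journal = vapply(recs, `[[`, "", "journal"),
    authors = lapply(recs, `[[`, "authors"),
    publicationTypes = lapply(recs, `[[`, "publicationTypes"),
    keywords = lapply(recs, `[[`, "keywords"),
    meshTerms = lapply(recs, `[[`, "meshTerms"),
    chemicals = lapply(recs, `[[`, "chemicals"),
    affiliations = lapply(recs, `[[`, "affiliations"))
}

.textAll <- function(node, xpath) {
  found <- xml2::xml_find_all(node, xpath)
  txt <- trimws(xml2::xml_text(found))
  txt[nzchar(txt)]
}

.parseCitation <- function(cite, pm) {
  title <- xml2::xml_text(
    xml2::xml_find_first(cite, "./Article/ArticleTitle"))
  if (is.na(title)) title <- ""
  abstract <- paste(.textAll(cite, "./Article/Abstract/AbstractText"),
                    collapse = " ")
  journal <- xml2::xml_text(
    xml2::xml_find_first(cite, "./Article/Journal/Title"))
  if (is.na(journal)) journal <- ""
  authorNodes <- xml2::xml_find_all(cite, "./Article/AuthorList/Author")
  authors <- vapply(authorNodes, function(a) {
    coll <- xml2::xml_text(xml2::xml_find_first(a, "./CollectiveName"))
    if (!is.na(coll) && nzchar(coll)) return(coll)
    last <- xml2::xml_text(xml2::xml_find_first(a, "./LastName"))
    fore <- xml2::xml_text(xml2::xml_find_first(a, "./ForeName"))
    trimws(paste(c(last[!is.na(last)], fore[!is.na(fore)]), collapse = " "))
  }, "")
  list(
    pmid = pm,
    title = trimws(title),
    abstract = trimws(abstract),
    journal = trimws(journal),
    authors = authors[nzchar(authors)],
    publicationTypes = .textAll(cite,
      "./Article/PublicationTypeList/PublicationType"),
    keywords = .textAll(cite, "./KeywordList/Keyword"),
    meshTerms = .textAll(cite,
      "./MeshHeadingList/MeshHeading/DescriptorName"),
    chemicals = .textAll(cite, "./ChemicalList/Chemical/NameOfSubstance"),
    affiliations = .textAll(cite,
      "./Article/AuthorList/Author/AffiliationInfo/Affiliation"))
}

#' Write a corpus as MEDLINE-format XML
#'
#' Emits one `PubmedArticle/MedlineCitation` element per record such that
#' [parsePubmedXML()] reproduces the corpus field-by-field. Empty abstracts
#' and empty metadata lists are omitted from the output.
#'
#' @param corpus a [DocumentCorpus-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCorpusXML <- function(corpus, path) {
  stopifnot(is(corpus, "DocumentCorpus"))
  root <- xml2::xml_new_root("PubmedArticleSet")
  for (i in seq_len(length(corpus))) {
    art <- xml2::xml_add_child(root, "PubmedArticle")
    cite <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cite, "PMID", corpus@pmid[i])
    a <- xml2::xml_add_child(cite, "Article")
    if (nzchar(corpus@journal[i])) {
      j <- xml2::xml_add_child(a, "Journal")
      xml2::xml_add_child(j, "Title", corpus@journal[i])
    }
    xml2::xml_add_child(a, "ArticleTitle", corpus@title[i])
    if (nzchar(corpus@abstract[i])) {
      ab <- xml2::xml_add_child(a, "Abstract")
      xml2::xml_add_child(ab, "AbstractText", corpus@abstract[i])
    }
    auths <- corpus@authors[[i]]
    affs <- corpus@affiliations[[i]]
    if (length(auths) || length(affs)) {
      al <- xml2::xml_add_child(a, "AuthorList")
      if (length(auths) == 0L && length(affs) > 0L) auths <- ""
      for (k in seq_along(auths)) {
        au <- xml2::xml_add_child(al, "Author")
        if (nzchar(auths[k]))
          xml2::xml_add_child(au, "CollectiveName", auths[k])
        if (k == 1L && length(affs)) {
          for (aff in affs) {
            ai <- xml2::xml_add_child(au, "AffiliationInfo")
            xml2::xml_add_child(ai, "Affiliation", aff)
          }
        }
      }
    }
    pts <- corpus@publicationTypes[[i]]
    if (length(pts)) {
      pl <- xml2::xml_add_child(a, "PublicationTypeList")
      for (pt in pts) xml2::xml_add_child(pl, "PublicationType", pt)
    }
    mesh <- corpus@meshTerms[[i]]
    if (length(mesh)) {
      ml <- xml2::xml_add_child(cite, "MeshHeadingList")
      for (m in mesh) {
        mh <- xml2::xml_add_child(ml, "MeshHeading")
        xml2::xml_add_child(mh, "DescriptorName", m)
      }
    }
    chem <- corpus@chemicals[[i]]
    if (length(chem)) {
      cl <- xml2::xml_add_child(cite, "ChemicalList")
      for (ch in chem) {
        cn <- xml2::xml_add_child(cl, "Chemical")
        xml2::xml_add_child(cn, "NameOfSubstance", ch)
      }
    }
    kw <- corpus@keywords[[i]]
    if (length(kw)) {
      kl <- xml2::xml_add_child(cite, "KeywordList")
      for (k in kw) xml2::xml_add_child(kl, "Keyword", k)
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

# ---- labels ------------------------------------------------------------

#' Canonical label levels
#' @return `c("NotRelevant", "Relevant")` (positive class last).
#' @export
labelLevels <- function() c("NotRelevant", "Relevant")

#' Normalise label strings to canonical values
#'
#' Case-insensitive, with internal whitespace collapsed, so `"Not Relevant"`,
#' `"not relevant"` and `"NotRelevant"` all map to `"NotRelevant"`.
#'
#' @param x character vector (or factor) of raw label strings.
#' @return factor with levels `NotRelevant`, `Relevant`; unknown strings
#'   become `NA`.
#' @export
canonicalLabels <- function(x) {
  key <- tolower(gsub("[[:space:]_-]+", "", as.character(x)))
  out <- rep(NA_character_, length(key))
  out[key == "relevant"] <- "Relevant"
  out[key == "notrelevant"] <- "NotRelevant"
  factor(out, levels = labelLevels())
}

#' Read a pmid/label table
#'
#' Reads a CSV with header columns `pmid` and `label`, normalising label
#' strings to the canonical `Relevant` / `NotRelevant` values.
#'
#' @param path CSV file path.
#' @return data.frame with character `pmid` and factor `label`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("pmid,label", "1,Relevant", "2,Not Relevant"), f)
#' readLabels(f)
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stop("no such label file: ", path)
  tab <- read.csv(path, colClasses = "character")
  if (!all(c("pmid", "label") %in% names(tab)))
    stop("label table must have 'pmid' and 'label' columns; found: ",
         paste(names(tab), collapse = ", "))
  lab <- canonicalLabels(tab$label)
  if (anyNA(lab)) {
    bad <- which(is.na(lab))
    stop("unknown label value(s) in row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(tab$label[bad]), collapse = ", "))
  }
  if (anyDuplicated(tab$pmid)) {
    dup <- unique(tab$pmid[duplicated(tab$pmid)])
    stop("duplicate pmid(s) in label table: ", paste(dup, collapse = ", "))
  }
  data.frame(pmid = tab$pmid, label = lab, stringsAsFactors = FALSE)
}

#' Write a pmid/label table
#' @param labels data.frame with columns `pmid` and `label`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeLabels <- function(labels, path) {
  stopifnot(all(c("pmid", "label") %in% names(labels)))
  write.csv(data.frame(pmid = labels$pmid,
                       label = as.character(labels$label)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Field availability and label prevalence of a corpus
#'
#' Availability of a field is `100 * (records with a non-empty value) /
#' (total records)`; prevalence of a label is `100 * (records with that
#' label) / (labelled records)`.
#'
#' @param corpus a non-empty [DocumentCorpus-class].
#' @param labels optional data.frame with `pmid` and `label` columns.
#' @return list with `availability` (data.frame field, percent) and
#'   `prevalence` (data.frame label, percent, or NULL when no labels given).
#' @export
corpusStats <- function(corpus, labels = NULL) {
  stopifnot(is(corpus, "DocumentCorpus"))
  if (length(corpus) == 0L) stop("corpus must be non-empty")
  n <- length(corpus)
  fields <- names(.FIELD_KEYS)
  pct <- vapply(fields, function(f) {
    v <- corpusField(corpus, f)
    present <- if (is.list(v)) lengths(v) > 0L else nzchar(v)
    100 * sum(present) / n
  }, 0)
  availability <- data.frame(field = fields, percent = unname(pct),
                             stringsAsFactors = FALSE)
  prevalence <- NULL
  if (!is.null(labels)) {
    lab <- canonicalLabels(labels$label)
    counts <- table(lab)
    prevalence <- data.frame(label = names(counts),
                             percent = 100 * as.numeric(counts) / sum(counts),
                             stringsAsFactors = FALSE)
  }
  list(availability = availability, prevalence = prevalence)
}

# ---- JSON-lines corpus persistence ------------------------------------

#' Write a corpus as JSON lines
#'
#' One JSON object per line with snake_case keys (`pmid`, `title`,
#' `abstract`, `journal`, `authors`, `publication_type`, `keywords`,
#' `mesh_terms`, `chemicals`, `affiliations`).
#'
#' @param corpus a [DocumentCorpus-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCorpusJSONL <- function(corpus, path) {
  stopifnot(is(corpus, "DocumentCorpus"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(length(corpus))) {
    rec <- list(pmid = corpus@pmid[i], title = corpus@title[i],
                abstract = corpus@abstract[i], journal = corpus@journal[i],
                authors = corpus@authors[[i]],
                publication_type = corpus@publicationTypes[[i]],
                keywords = corpus@keywords[[i]],
                mesh_terms = corpus@meshTerms[[i]],
                chemicals = corpus@chemicals[[i]],
                affiliations = corpus@affiliations[[i]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = FALSE), con)
  }
  invisible(path)
}

#' Read a JSON-lines corpus written by [writeCorpusJSONL()]
#' @param path file path.
#' @return a [DocumentCorpus-class].
#' @export
readCorpusJSONL <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  recs <- lapply(lines, jsonlite::fromJSON)
  chr1 <- function(key) vapply(recs, function(r)
    if (length(r[[key]])) paste(r[[key]], collapse = " ") else "", "")
  lst <- function(key) lapply(recs, function(r) as.character(r[[key]]))
  DocumentCorpus(pmid = chr1("pmid"), title = chr1("title"),
                 abstract = chr1("abstract"), journal = chr1("journal"),
                 authors = lst("authors"),
                 publicationTypes = lst("publication_type"),
                 keywords = lst("keywords"), meshTerms = lst("mesh_terms"),
                 chemicals = lst("chemicals"),
                 affiliations = lst("affiliations"))
}
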