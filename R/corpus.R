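# Corpus ingestion, sentence splitting, and term-based subsetting.

#' Default abbreviation guard list for the sentence splitter
#' @return character vector of abbreviations (each ending in ".").
#' @export
defaultAbbreviations <- function() {
  c("E.", "sp.", "spp.", "et al.", "Fig.", "vs.", "e.g.", "i.e.",
    "approx.", "St.")
}

#' Default surface variants of the generic term "vaccine"
#' @return character vector of vaccine term variants.
#' @export
defaultVaccineVariants <- function() {
  c("vaccine", "vaccines", "vaccination", "vaccinations",
    "vaccinated", "vaccinating")
}

#' Read an abstract corpus
#'
#' Reads document records (id, title, abstract) from a 3-column TSV with
#' header `doc_id`/`title`/`abstract`, or from MEDLINE-style XML
#' (`PubmedArticle` elements with `PMID`, `ArticleTitle`, `AbstractText`).
#'
#' @param path input file.
#' @param format `"tsv"` or `"medline_xml"`.
#' @return data.frame with columns `doc_id`, `title`, `abstract`, one row
#'   per article in file order.
#' @export
readCorpus <- function(path, format = c("tsv", "medline_xml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path)
  docs <- switch(format,
    tsv = .readCorpusTsv(path),
    medline_xml = .readCorpusXml(path))
  if (!nrow(docs)) stop("corpus is empty: ", path)
  if (any(!nzchar(docs$doc_id)))
    stop("empty doc_id at row ", which(!nzchar(docs$doc_id))[1])
  if (anyDuplicated(docs$doc_id))
    stop("duplicate doc_id: ", docs$doc_id[duplicated(docs$doc_id)][1])
  bad <- !nzchar(docs$title) & !nzchar(docs$abstract)
  if (any(bad))
    stop("document with empty title and abstract: ", docs$doc_id[bad][1])
  docs
}

.readCorpusTsv <- function(path) {
  d <- utils::read.delim(path, colClasses = "character", quote = "",
                         check.names = FALSE, na.strings = NULL)
  need <- c("doc_id", "title", "abstract")
  if (!all(need %in% colnames(d)))
    stop("TSV corpus must have header columns doc_id/title/abstract; got: ",
         paste(colnames(d), collapse = ", "))
  d <- d[, need]
  rownames(d) <- NULL
  d
}

.readCorpusXml <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  if (!length(arts)) stop("no PubmedArticle elements in ", path)
  recs <- lapply(seq_along(arts), function(i) {
    a <- arts[[i]]
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//PMID"))
    if (is.na(pmid) || !nzchar(pmid))
      stop("PubmedArticle element ", i, " has no PMID")
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    abst <- paste(xml2::xml_text(xml2::xml_find_all(a, ".//AbstractText")),
                  collapse = " ")
    data.frame(doc_id = pmid,
               title = ifelse(is.na(title), "", title),
               abstract = abst, stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Write a corpus back to TSV
#' @param docs corpus data.frame (`doc_id`, `title`, `abstract`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCorpus <- function(docs, path) {
  utils::write.table(docs[, c("doc_id", "title", "abstract")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Split one text block at [.?!]+ followed by whitespace and [A-Z0-9],
# guarded by the abbreviation list. Returns start/end (1-based inclusive)
# relative to the block.
.splitBlock <- function(text, abbreviations) {
  if (!nzchar(text)) return(data.frame(start = integer(), end = integer()))
  m <- gregexpr("[.?!]+(?=[[:space:]]+[A-Z0-9])", text, perl = TRUE)[[1]]
  breaks <- integer()
  if (m[1] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L
    for (e in ends) {
      prefix <- substr(text, 1L, e)
      guarded <- any(vapply(abbreviations, function(ab) {
        if (!endsWith(prefix, ab)) return(FALSE)
        before <- nchar(prefix) - nchar(ab)
        before == 0L || grepl("[^A-Za-z0-9]",
                              substr(prefix, before, before))
      }, logical(1)))
      if (!guarded) breaks <- c(breaks, e)
    }
  }
  bounds <- c(0L, breaks, nchar(text))
  out <- data.frame(start = head(bounds, -1) + 1L, end = bounds[-1])
  # trim surrounding whitespace per sentence
  for (i in seq_len(nrow(out))) {
    while (out$start[i] <= out$end[i] &&
           grepl("^[[:space:]]$", substr(text, out$start[i], out$start[i])))
      out$start[i] <- out$start[i] + 1L
    while (out$end[i] >= out$start[i] &&
           grepl("^[[:space:]]$", substr(text, out$end[i], out$end[i])))
      out$end[i] <- out$end[i] - 1L
  }
  out[out$start <= out$end, , drop = FALSE]
}

#' Split a document into sentences with stable character offsets
#'
#' Splits at `.`, `?` or `!` followed by whitespace and an uppercase letter
#' or digit, guarded by an abbreviation list. Offsets are 0-based half-open
#' into the concatenation `title + "\n" + abstract`; title sentences precede
#' abstract sentences.
#'
#' @param doc one-row corpus data.frame, or a list with `doc_id`, `title`,
#'   `abstract`.
#' @param abbreviations abbreviation guard list.
#' @return data.frame with columns `doc_id`, `sent_index`, `text`,
#'   `char_start`, `char_end`.
#' @export
splitSentences <- function(doc, abbreviations = defaultAbbreviations()) {
  title <- doc$title
  abstract <- doc$abstract
  src <- paste0(title, "\n", abstract)
  spans <- .splitBlock(title, abbreviations)
  aspans <- .splitBlock(abstract, abbreviations)
  if (nrow(aspans)) {
    off <- nchar(title) + 1L
    aspans$start <- aspans$start + off
    aspans$end <- aspans$end + off
  }
  spans <- rbind(spans, aspans)
  if (!nrow(spans)) {
    return(data.frame(doc_id = character(), sent_index = integer(),
                      text = character(), char_start = integer(),
                      char_end = integer(), stringsAsFactors = FALSE))
  }
  data.frame(doc_id = doc$doc_id,
             sent_index = seq_len(nrow(spans)) - 1L,
             text = substring(src, spans$start, spans$end),
             char_start = spans$start - 1L,
             char_end = spans$end,
             stringsAsFactors = FALSE)
}

#' Split every document of a corpus into sentences
#' @param docs corpus data.frame.
#' @inheritParams splitSentences
#' @return row-bound sentence data.frame for all documents.
#' @export
splitCorpusSentences <- function(docs,
                                 abbreviations = defaultAbbreviations()) {
  out <- lapply(seq_len(nrow(docs)),
                function(i) splitSentences(docs[i, ], abbreviations))
  do.call(rbind, out)
}

#' Select the documents matching at least one term
#'
#' A document matches when its title or abstract contains one of the terms
#' at token boundaries, case-insensitively (multi-word terms tolerate
#' hyphen/whitespace variation between words).
#'
#' @param docs corpus data.frame.
#' @param terms character vector of matcher terms (surface-variant list or
#'   ontology labels/synonyms).
#' @return the matching subset of `docs`, input order preserved.
#' @export
subsetCorpus <- function(docs, terms) {
  terms <- terms[nzchar(trimws(terms))]
  if (!length(terms)) stop("term matcher must not be empty")
  keep <- vapply(seq_len(nrow(docs)), function(i) {
    text <- paste(docs$title[i], docs$abstract[i], sep = "\n")
    any(vapply(terms, function(tm) termBoundaryMatch(text, tm), logical(1)))
  }, logical(1))
  docs[keep, , drop = FALSE]
}
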