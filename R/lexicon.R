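# Gene lexicon loading and index construction.

.indexKeysFor <- function(form) {
  keys <- normSurface(form)
  # a hyphenated symbol form is additionally indexed with the hyphen
  # removed, so IL-6 and IL6 resolve to the same entry
  if (grepl("[-‐‑‒–—]", form)) {
    keys <- c(keys, normSurface(gsub("[-‐‑‒–—]", "", form)))
  }
  unique(keys[nzchar(keys)])
}

#' Load a gene lexicon from TSV
#'
#' Expects columns `symbol`, `name`, `synonyms` (pipe-separated, possibly
#' empty). Builds a lookup index over normalized surface forms: lowercase,
#' Greek letters spelled out, hyphen/whitespace runs collapsed to one
#' space; symbol-like hyphenated forms are also indexed without the hyphen.
#'
#' @param path TSV file.
#' @return a [GeneLexicon-class] object.
#' @export
loadGeneLexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  d <- utils::read.delim(path, colClasses = "character", quote = "",
                         check.names = FALSE, na.strings = NULL)
  need <- c("symbol", "name", "synonyms")
  if (!all(need %in% colnames(d)))
    stop("gene lexicon TSV needs header columns symbol/name/synonyms")
  if (!nrow(d)) stop("gene lexicon is empty: ", path)
  if (anyDuplicated(d$symbol))
    stop("duplicate official symbol: ", d$symbol[duplicated(d$symbol)][1])
  buildGeneLexicon(d[, need])
}

#' Build a gene lexicon from an in-memory entry table
#' @param entries data.frame with columns `symbol`, `name`, `synonyms`.
#' @return a [GeneLexicon-class] object.
#' @export
buildGeneLexicon <- function(entries) {
  index <- list()
  rawForms <- list()
  maxTok <- 1L
  for (i in seq_len(nrow(entries))) {
    sym <- entries$symbol[i]
    syns <- strsplit(entries$synonyms[i], "|", fixed = TRUE)[[1]]
    forms <- unique(c(sym, entries$name[i], syns))
    forms <- forms[nzchar(trimws(forms))]
    for (f in forms) {
      for (key in .indexKeysFor(f)) {
        index[[key]] <- unique(c(index[[key]], sym))
        rawForms[[key]] <- unique(c(rawForms[[key]], f))
        maxTok <- max(maxTok,
                      length(strsplit(key, " ", fixed = TRUE)[[1]]))
      }
    }
  }
  new("GeneLexicon", entries = entries, index = index,
      rawForms = rawForms, maxTokens = maxTok)
}

#' Look up a surface form in the lexicon
#'
#' Applies the matching rules: surfaces of 2 characters or fewer must equal
#' an indexed raw form case-sensitively; an ambiguous surface (mapping to
#' more than one official symbol) is dropped unless it equals one of the
#' official symbols exactly.
#'
#' @param lex a [GeneLexicon-class].
#' @param surface the candidate surface string as it appears in text.
#' @return the resolved official symbol, or `NA_character_`.
#' @export
lookupGene <- function(lex, surface) {
  key <- normSurface(surface)
  syms <- lex@index[[key]]
  if (is.null(syms)) return(NA_character_)
  if (nchar(surface) <= 2L && !(surface %in% lex@rawForms[[key]]))
    return(NA_character_)
  if (length(syms) > 1L) {
    if (surface %in% syms) return(surface)
    return(NA_character_)
  }
  syms
}
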