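# Candidate interaction-sentence selection.

#' Default interaction keyword stems
#'
#' Reads the packaged keyword list (one entry per line, `#` comments).
#' The list is user-replaceable; entries are matched case-insensitively at
#' token boundaries after light stemming.
#'
#' @param path keyword file; defaults to the packaged list.
#' @return character vector of keywords.
#' @export
defaultKeywords <- function(path = system.file("extdata",
                                               "interaction_keywords.txt",
                                               package = "condl")) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

# Return the surface of the first sentence token whose stem matches a
# keyword stem, or NA.
.matchKeyword <- function(text, keywordStems) {
  toks <- tokenizeText(text)
  if (!nrow(toks)) return(NA_character_)
  stems <- lightStem(toks$token)
  hit <- which(stems %in% keywordStems)
  if (!length(hit)) return(NA_character_)
  toks$token[hit[1]]
}

#' Find candidate interaction pairs in a tagged sentence
#'
#' A sentence is a candidate source when it contains at least one
#' interaction keyword (token-boundary, case-insensitive, light-stemmed
#' match). Each unordered pair of mentions with distinct `norm_id` becomes
#' a candidate: `gene_gene` for two genes, `gene_vaccine` for one gene and
#' one vaccine mention. Vaccine-vaccine pairs are not candidates.
#'
#' @param sentence one-row sentence data.frame (`doc_id`, `sent_index`,
#'   `text`).
#' @param mentions mentions of that sentence (see [tagSentence()]).
#' @param keywords keyword list (see [defaultKeywords()]).
#' @return candidate data.frame with one row per pair: the mention spans
#'   (`a_*`, `b_*`), matched `keyword`, and `pair_kind`.
#' @export
findCandidates <- function(sentence, mentions, keywords = defaultKeywords()) {
  if (!length(keywords)) stop("keyword list must not be empty")
  empty <- data.frame(doc_id = character(), sent_index = integer(),
                      a_norm = character(), a_etype = character(),
                      a_start = integer(), a_end = integer(),
                      b_norm = character(), b_etype = character(),
                      b_start = integer(), b_end = integer(),
                      keyword = character(), pair_kind = character(),
                      stringsAsFactors = FALSE)
  if (is.null(mentions) || nrow(mentions) < 2L) return(empty)
  kw <- .matchKeyword(sentence$text, unique(lightStem(keywords)))
  if (is.na(kw)) return(empty)
  isGene <- mentions$etype == "gene"
  out <- list()
  n <- nrow(mentions)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (mentions$norm_id[i] == mentions$norm_id[j]) next
      ng <- sum(isGene[c(i, j)])
      kind <- if (ng == 2L) "gene_gene"
              else if (ng == 1L) "gene_vaccine"
              else next
      out[[length(out) + 1L]] <- data.frame(
        doc_id = sentence$doc_id, sent_index = sentence$sent_index,
        a_norm = mentions$norm_id[i], a_etype = mentions$etype[i],
        a_start = mentions$char_start[i], a_end = mentions$char_end[i],
        b_norm = mentions$norm_id[j], b_etype = mentions$etype[j],
        b_start = mentions$char_start[j], b_end = mentions$char_end[j],
        keyword = kw, pair_kind = kind, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Find candidates across a whole tagged corpus
#' @param sentences sentence data.frame.
#' @param mentions mention data.frame for all sentences.
#' @param keywords keyword list.
#' @return row-bound candidate data.frame.
#' @export
findCorpusCandidates <- function(sentences, mentions,
                                 keywords = defaultKeywords()) {
  key <- paste0(mentions$doc_id, "#", mentions$sent_index)
  out <- lapply(seq_len(nrow(sentences)), function(i) {
    sk <- paste0(sentences$doc_id[i], "#", sentences$sent_index[i])
    findCandidates(sentences[i, ], mentions[key == sk, , drop = FALSE],
                   keywords)
  })
  do.call(rbind, out)
}
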