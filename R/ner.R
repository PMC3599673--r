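# Dictionary- and rule-based tagging of gene and vaccine mentions.

# Build the vaccine-specific dictionary: normalized key -> term id.
# By default only leaf terms under the root are used (specific vaccine
# names at the bottom of the hierarchy); allTerms = TRUE uses every
# descendant of the root.
.vaccineIndex <- function(onto, rootId, allTerms = FALSE) {
  ids <- if (allTerms) ontologyDescendants(onto, rootId)
         else leafTerms(onto, rootId)
  index <- list()
  maxTok <- 1L
  for (id in ids) {
    forms <- c(onto@labels[[id]], onto@synonyms[[id]])
    forms <- forms[!is.na(forms) & nzchar(forms)]
    for (f in forms) {
      key <- normSurface(f)
      if (!nzchar(key)) next
      index[[key]] <- unique(c(index[[key]], id))
      maxTok <- max(maxTok, length(strsplit(key, " ", fixed = TRUE)[[1]]))
    }
  }
  list(index = index, maxTokens = maxTok)
}

#' Tag gene and vaccine mentions in one sentence
#'
#' Scans left to right over token boundaries; the longest indexed match
#' wins and matching resumes after it, so mentions never overlap. Gene
#' surfaces are normalized to official symbols under the lexicon rules
#' (case-sensitive match for surfaces of <= 2 characters; ambiguous
#' surfaces dropped unless equal to an official symbol). Ontology
#' label/synonym matches are typed `vaccine_specific` with the term id as
#' `norm_id`; generic variant matches are typed `vaccine_general` with
#' `norm_id` `"vaccine"`. At equal span length genes take precedence over
#' vaccine terms.
#'
#' @param sentence one-row sentence data.frame (`doc_id`, `sent_index`,
#'   `text`) as produced by [splitSentences()].
#' @param lex a [GeneLexicon-class].
#' @param onto an [Ontology-class], or `NULL` to skip vaccine tagging.
#' @param vaccineVariants generic-term surface list
#'   (see [defaultVaccineVariants()]).
#' @param rootId ontology root term id; defaults to the term labelled
#'   "vaccine".
#' @param vaccineLeavesOnly tag only leaf terms under the root (default)
#'   or all descendants.
#' @return mention data.frame: `doc_id`, `sent_index`, `char_start`,
#'   `char_end` (0-based half-open, sentence-local), `surface`, `etype`,
#'   `norm_id`, sorted by `char_start`.
#' @export
tagSentence <- function(sentence, lex, onto = NULL,
                        vaccineVariants = defaultVaccineVariants(),
                        rootId = NULL, vaccineLeavesOnly = TRUE) {
  text <- sentence$text
  toks <- tokenizeText(text)
  if (!nrow(toks)) return(.emptyMentions())
  vidx <- list(index = list(), maxTokens = 0L)
  if (!is.null(onto)) {
    if (is.null(rootId)) rootId <- termByLabel(onto, "vaccine")
    vidx <- .vaccineIndex(onto, rootId, allTerms = !vaccineLeavesOnly)
  }
  variantKeys <- normSurface(vaccineVariants)
  maxLen <- max(lex@maxTokens, vidx$maxTokens, 1L)
  n <- nrow(toks)
  out <- list()
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (L in seq(min(maxLen, n - i + 1L), 1L)) {
      j <- i + L - 1L
      surface <- substr(text, toks$start[i], toks$end[j])
      key <- normSurface(surface)
      # gene first at equal length, then specific vaccine, then generic
      sym <- lookupGene(lex, surface)
      hit <- NULL
      if (!is.na(sym)) {
        hit <- list(etype = "gene", norm = sym)
      } else if (!is.null(vidx$index[[key]]) &&
                 length(vidx$index[[key]]) == 1L) {
        hit <- list(etype = "vaccine_specific", norm = vidx$index[[key]])
      } else if (L == 1L && key %in% variantKeys) {
        hit <- list(etype = "vaccine_general", norm = "vaccine")
      }
      if (!is.null(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          doc_id = sentence$doc_id, sent_index = sentence$sent_index,
          char_start = toks$start[i] - 1L, char_end = toks$end[j],
          surface = surface, etype = hit$etype, norm_id = hit$norm,
          stringsAsFactors = FALSE)
        i <- j + 1L
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  if (!length(out)) return(.emptyMentions())
  do.call(rbind, out)
}

#' Tag every sentence of a corpus
#'
#' @param sentences sentence data.frame from [splitCorpusSentences()].
#' @inheritParams tagSentence
#' @return row-bound mention data.frame.
#' @export
tagCorpus <- function(sentences, lex, onto = NULL,
                      vaccineVariants = defaultVaccineVariants(),
                      rootId = NULL, vaccineLeavesOnly = TRUE) {
  if (!is.null(onto) && is.null(rootId)) rootId <- termByLabel(onto, "vaccine")
  out <- lapply(seq_len(nrow(sentences)), function(i)
    tagSentence(sentences[i, ], lex, onto, vaccineVariants, rootId,
                vaccineLeavesOnly))
  res <- do.call(rbind, out)
  if (is.null(res)) .emptyMentions() else res
}

#' Write mentions to TSV
#' @param mentions mention data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMentions <- function(mentions, path) {
  utils::write.table(mentions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
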