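# Small in-code fixture builders shared across test files.

writeTempTsv <- function(df, ...) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE, ...)
  f
}

writeTempLines <- function(lines, ext = ".txt") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

toyLexicon <- function() {
  buildGeneLexicon(data.frame(
    symbol = c("IL6", "STAT3", "TNF", "AB"),
    name = c("interleukin 6", "signal transducer and activator of transcription 3",
             "tumor necrosis factor", "antigen binder"),
    synonyms = c("IL-6|BSF2", "", "TNF-alpha", ""),
    stringsAsFactors = FALSE))
}

toyOntologyLines <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: V:1", "name: vaccine", "",
    "[Term]", "id: V:2", "name: live vaccine", "is_a: V:1", "",
    "[Term]", "id: V:3", "name: BCG vaccine", "is_a: V:2", "",
    "[Term]", "id: V:4", "name: flu vaccine", "is_a: V:1", "")
}

toyOntology <- function() loadObo(writeTempLines(toyOntologyLines(), ".obo"))

sentenceRow <- function(text, doc_id = "d1", sent_index = 0L) {
  data.frame(doc_id = doc_id, sent_index = sent_index, text = text,
             stringsAsFactors = FALSE)
}

# "ENTA activates ENTB." with the classic nsubj/dobj analysis
toyParseLines <- function(doc_id = "d1", sent_index = 0L,
                          a = "ENTA", b = "ENTB", verb = "activates",
                          lemma = "activate") {
  text <- paste0(a, " ", verb, " ", b, ".")
  c(paste0("# doc_id = ", doc_id),
    paste0("# sent_index = ", sent_index),
    paste0("# text = ", text),
    paste(1, a, tolower(a), "_", "_", "_", 2, "nsubj", "_", "_", sep = "\t"),
    paste(2, verb, lemma, "_", "_", "_", 0, "root", "_", "_", sep = "\t"),
    paste(3, b, tolower(b), "_", "_", "_", 2, "dobj", "_", "_", sep = "\t"),
    paste(4, ".", ".", "_", "_", "_", 2, "punct", "_", "_", sep = "\t"),
    "")
}

# random labelled dependency tree as a DepParse, plus its undirected edges
randomParse <- function(n) {
  head <- integer(n)
  for (i in seq(2L, length.out = max(0L, n - 1L))) head[i] <- sample.int(i - 1L, 1L)
  tokens <- data.frame(tid = seq_len(n),
                       form = paste0("w", seq_len(n)),
                       lemma = paste0("w", seq_len(n)),
                       head = head,
                       deprel = sample(c("nsubj", "dobj", "prep", "amod"),
                                       n, replace = TRUE),
                       stringsAsFactors = FALSE)
  tokens$deprel[tokens$head == 0L] <- "root"
  list(doc_id = "d1", sent_index = 0L, text = NA_character_,
       tokens = tokens)
}

# simple named networks
p3Network <- function() {
  makeNetwork(data.frame(id = c("a", "b", "c"), ntype = "gene"),
              data.frame(a = c("a", "b"), b = c("b", "c"),
                         n_sentences = 1L, max_score = 1,
                         source_tag = "literature"))
}

starNetwork <- function(nLeaves = 3L) {
  leaves <- paste0("leaf", seq_len(nLeaves))
  makeNetwork(
    data.frame(id = c("hub", leaves), ntype = "gene"),
    data.frame(a = rep("hub", nLeaves), b = leaves, n_sentences = 1L,
               max_score = 1, source_tag = "literature"))
}

triangleNetwork <- function() {
  makeNetwork(data.frame(id = c("a", "b", "c"), ntype = "gene"),
              data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"),
                         n_sentences = 1L, max_score = 1,
                         source_tag = "literature"))
}

# scored-candidate row builder for network assembly tests
scoredRow <- function(a, b, doc = "d1", sent = 0L, score = 1,
                      aType = "gene", bType = "gene",
                      kind = "gene_gene") {
  data.frame(doc_id = doc, sent_index = sent, a_norm = a, a_etype = aType,
             a_start = 0L, a_end = 1L, b_norm = b, b_etype = bType,
             b_start = 2L, b_end = 3L, keyword = "binds",
             pair_kind = kind, path = "ENTITYA nsubj< bind dobj> ENTITYB",
             score = score, is_positive = score > 0,
             stringsAsFactors = FALSE)
}
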