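# CoNLL-U dependency-parse reading.

#' Read dependency parses from a CoNLL-U file
#'
#' Standard 10-column CoNLL-U. Sentence blocks must carry `# doc_id = ...`
#' and `# sent_index = ...` metadata lines (an optional `# text = ...` line
#' is kept for mention-token alignment). Multiword-token and empty-node
#' lines (ids containing `-` or `.`) are skipped. Each block must have
#' consecutive token ids from 1, exactly one root (head 0), and heads
#' referencing existing ids.
#'
#' @param path CoNLL-U file.
#' @return list of parses; each is a list with `doc_id`, `sent_index`,
#'   `text` (may be `NA`), and `tokens` (data.frame `tid`, `form`, `lemma`,
#'   `head`, `deprel`).
#' @export
readConllu <- function(path) {
  if (!file.exists(path)) stop("CoNLL-U file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  parses <- list()
  meta <- list(doc_id = NA_character_, sent_index = NA_integer_,
               text = NA_character_)
  rows <- list()
  flush <- function() {
    if (!length(rows)) return()
    tok <- do.call(rbind, rows)
    where <- sprintf("(doc %s, sentence %s)", meta$doc_id, meta$sent_index)
    if (is.na(meta$doc_id) || is.na(meta$sent_index))
      stop("CoNLL-U block without doc_id/sent_index metadata near parse ",
           length(parses) + 1L)
    if (!identical(tok$tid, seq_len(nrow(tok))))
      stop("non-consecutive token ids ", where)
    if (sum(tok$head == 0L) != 1L)
      stop("expected exactly one root token ", where)
    bad <- tok$head != 0L & !(tok$head %in% tok$tid)
    if (any(bad))
      stop("head points to absent token id ", tok$head[bad][1], " ", where)
    if (any(tok$head == tok$tid))
      stop("token is its own head ", where)
    parses[[length(parses) + 1L]] <<- list(
      doc_id = meta$doc_id, sent_index = meta$sent_index,
      text = meta$text, tokens = tok)
    rows <<- list()
    meta <<- list(doc_id = NA_character_, sent_index = NA_integer_,
                  text = NA_character_)
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { flush(); next }
    if (startsWith(ln, "#")) {
      kv <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", ln))[[1]]
      if (length(kv) == 3L) {
        key <- kv[2]; val <- trimws(kv[3])
        if (key == "doc_id") meta$doc_id <- val
        if (key == "sent_index") meta$sent_index <- as.integer(val)
        if (key == "text") meta$text <- val
      }
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop("malformed CoNLL-U token line (", length(f), " columns): ", ln)
    if (grepl("[-.]", f[1])) next  # multiword token / empty node
    rows[[length(rows) + 1L]] <- data.frame(
      tid = as.integer(f[1]), form = f[2], lemma = f[3],
      head = as.integer(f[7]), deprel = f[8], stringsAsFactors = FALSE)
  }
  flush()
  parses
}

#' Index parses by document and sentence
#' @param parses list from [readConllu()].
#' @return named list keyed by `"doc_id#sent_index"`.
#' @export
indexParses <- function(parses) {
  setNames(parses, vapply(parses, function(p)
    paste0(p$doc_id, "#", p$sent_index), character(1)))
}
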