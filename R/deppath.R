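# Shortest dependency paths between entity mentions.

# Locate each token's character span in the sentence text by sequential
# search; falls back to whitespace-joined reconstruction offsets when the
# text is unavailable.
.tokenOffsets <- function(tokens, text) {
  n <- nrow(tokens)
  start <- integer(n); end <- integer(n)
  if (is.na(text)) {
    pos <- 1L
    for (i in seq_len(n)) {
      start[i] <- pos
      end[i] <- pos + nchar(tokens$form[i]) - 1L
      pos <- end[i] + 2L
    }
  } else {
    cursor <- 1L
    for (i in seq_len(n)) {
      hit <- regexpr(tokens$form[i], substr(text, cursor, nchar(text)),
                     fixed = TRUE)
      if (hit == -1L)
        stop("token form not found in sentence text: ", tokens$form[i])
      start[i] <- cursor + as.integer(hit) - 1L
      end[i] <- start[i] + nchar(tokens$form[i]) - 1L
      cursor <- end[i] + 1L
    }
  }
  cbind(start = start, end = end)
}

# Align a mention (0-based half-open span) to its head token id:
# among tokens overlapping the span, prefer the one whose head lies
# outside the mention; ties and fallbacks resolve to the rightmost.
.alignMention <- function(tokens, offsets, char_start, char_end) {
  s1 <- char_start + 1L  # 1-based inclusive
  e1 <- char_end
  ov <- which(offsets[, "start"] <= e1 & offsets[, "end"] >= s1)
  if (!length(ov)) stop("mention not alignable to any token (span ",
                        char_start, "-", char_end, ")")
  outside <- ov[!(tokens$head[ov] %in% tokens$tid[ov])]
  if (length(outside)) max(outside) else max(ov)
}

# Tree path (sequence of token ids) between two tokens via the LCA of
# their head chains.
.treePath <- function(tokens, a, b) {
  parent <- integer(nrow(tokens))
  parent[tokens$tid] <- tokens$head
  chain <- function(x) {
    out <- x
    while (parent[x] != 0L) { x <- parent[x]; out <- c(out, x) }
    out
  }
  ca <- chain(a); cb <- chain(b)
  lca <- intersect(ca, cb)[1]
  if (is.na(lca)) stop("tokens lie in disconnected parse components")
  up <- ca[seq_len(which(ca == lca))]
  down <- rev(cb[seq_len(which(cb == lca) - 1L)])
  c(up, down)
}

#' Shortest dependency path between two mentions
#'
#' Extracts the unique tree path between the head tokens of two mentions
#' over the undirected dependency tree. Node tokens are lowercase lemmas
#' (form when the lemma is `_`), with the endpoints replaced by `ENTITYA` /
#' `ENTITYB` and any other token covered by a tagged mention replaced by
#' `ENTITYX`. Edge tokens are the dependency relations suffixed with a
#' traversal direction marker: `<` when the step moves from a dependent to
#' its head, `>` when it moves from a head to its dependent.
#'
#' @param parse one parse from [readConllu()].
#' @param a,b one-row mention data.frames with sentence-local `char_start`,
#'   `char_end`.
#' @param mentions optional full mention table for the sentence, used for
#'   `ENTITYX` substitution of other tagged entities on the path.
#' @return list with `sequence` (alternating node/edge tokens, starting
#'   `ENTITYA`, ending `ENTITYB`), `nodeTokens`, `edgeTokens`.
#' @export
shortestDepPath <- function(parse, a, b, mentions = NULL) {
  tokens <- parse$tokens
  offsets <- .tokenOffsets(tokens, parse$text)
  ta <- .alignMention(tokens, offsets, a$char_start, a$char_end)
  tb <- .alignMention(tokens, offsets, b$char_start, b$char_end)
  ta <- tokens$tid[ta]; tb <- tokens$tid[tb]
  if (ta == tb)
    stop("degenerate pair: both mentions align to the same token")
  ids <- .treePath(tokens, ta, tb)
  entityTids <- integer()
  if (!is.null(mentions) && nrow(mentions)) {
    s1 <- mentions$char_start + 1L
    e1 <- mentions$char_end
    for (k in seq_len(nrow(mentions))) {
      covered <- which(offsets[, "start"] <= e1[k] &
                       offsets[, "end"] >= s1[k])
      entityTids <- union(entityTids, tokens$tid[covered])
    }
  }
  nodeTok <- vapply(ids, function(tid) {
    if (tid == ta) return("ENTITYA")
    if (tid == tb) return("ENTITYB")
    if (tid %in% entityTids) return("ENTITYX")
    row <- which(tokens$tid == tid)
    lem <- tokens$lemma[row]
    tolower(if (lem == "_" || !nzchar(lem)) tokens$form[row] else lem)
  }, character(1))
  edgeTok <- character(length(ids) - 1L)
  for (k in seq_len(length(ids) - 1L)) {
    u <- ids[k]; v <- ids[k + 1L]
    ru <- which(tokens$tid == u); rv <- which(tokens$tid == v)
    if (tokens$head[rv] == u) {
      edgeTok[k] <- paste0(tokens$deprel[rv], ">")   # toward dependent
    } else if (tokens$head[ru] == v) {
      edgeTok[k] <- paste0(tokens$deprel[ru], "<")   # toward head
    } else stop("path step without a connecting arc (internal error)")
  }
  seqTok <- character(2L * length(ids) - 1L)
  seqTok[seq(1L, length(seqTok), by = 2L)] <- nodeTok
  if (length(edgeTok)) seqTok[seq(2L, length(seqTok), by = 2L)] <- edgeTok
  list(sequence = seqTok, nodeTokens = nodeTok, edgeTokens = edgeTok)
}

#' Extract dependency paths for all candidates of a corpus
#'
#' @param candidates candidate data.frame from [findCorpusCandidates()].
#' @param parses indexed parses from [indexParses()].
#' @param mentions full mention table (for `ENTITYX` substitution).
#' @return `candidates` with an added `path` column (sequence tokens joined
#'   by spaces); candidates whose sentence lacks a parse or whose pair is
#'   degenerate are dropped with a warning count attribute `n_dropped`.
#' @export
extractPaths <- function(candidates, parses, mentions = NULL) {
  paths <- character(nrow(candidates))
  keep <- logical(nrow(candidates))
  mkey <- if (!is.null(mentions))
    paste0(mentions$doc_id, "#", mentions$sent_index) else character()
  for (i in seq_len(nrow(candidates))) {
    key <- paste0(candidates$doc_id[i], "#", candidates$sent_index[i])
    p <- parses[[key]]
    if (is.null(p)) next
    sm <- if (!is.null(mentions)) mentions[mkey == key, , drop = FALSE]
          else NULL
    a <- data.frame(char_start = candidates$a_start[i],
                    char_end = candidates$a_end[i])
    b <- data.frame(char_start = candidates$b_start[i],
                    char_end = candidates$b_end[i])
    dp <- tryCatch(shortestDepPath(p, a, b, sm), error = function(e) NULL)
    if (is.null(dp)) next
    paths[i] <- paste(dp$sequence, collapse = " ")
    keep[i] <- TRUE
  }
  out <- candidates[keep, , drop = FALSE]
  out$path <- paths[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
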