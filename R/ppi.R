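# Comparison against an external protein-protein interaction network.

#' Read a PPI edge list
#'
#' Reads a TSV of interactor gene symbols (first two columns used; no
#' header by default, HPRD-style). Symbols are normalized through the gene
#' lexicon; rows whose symbols do not resolve are counted and skipped.
#' Undirected duplicates collapse and self-interactions are dropped.
#'
#' @param path TSV file.
#' @param lex a [GeneLexicon-class].
#' @param header does the file have a header row?
#' @return data.frame with columns `a`, `b` (`a < b`); attribute
#'   `n_unmapped` counts the skipped rows.
#' @export
readPpi <- function(path, lex, header = FALSE) {
  d <- utils::read.delim(path, header = header, colClasses = "character",
                         quote = "", na.strings = NULL)
  if (ncol(d) < 2L) stop("PPI file needs at least 2 columns")
  unmapped <- 0L
  pairs <- list()
  for (i in seq_len(nrow(d))) {
    a <- lookupGene(lex, d[i, 1]); b <- lookupGene(lex, d[i, 2])
    if (is.na(a) || is.na(b)) { unmapped <- unmapped + 1L; next }
    if (a == b) next
    pairs[[length(pairs) + 1L]] <- c(min(a, b), max(a, b))
  }
  if (length(pairs)) {
    m <- unique(do.call(rbind, pairs))
    out <- data.frame(a = m[, 1], b = m[, 2], stringsAsFactors = FALSE)
    out <- out[order(out$a, out$b), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE)
  }
  attr(out, "n_unmapped") <- unmapped
  out
}

#' Overlap a literature network with a PPI edge list
#'
#' Compares the gene-gene edges of the literature network against the PPI
#' edges. With `restrictToLitGenes = TRUE` (the default), PPI edges with
#' any endpoint outside the literature gene set are excluded before
#' comparison. Returns overlap counts and a merged network whose edges are
#' tagged `literature`, `ppi`, or `both`; gene-vaccine edges pass through
#' untouched with their literature tag.
#'
#' @param litNet an [InteractionNetwork-class].
#' @param ppiEdges data.frame from [readPpi()] (columns `a`, `b`).
#' @param restrictToLitGenes restrict PPI edges to literature genes first.
#' @return list with `counts` (named: `lit_only`, `ppi_only`, `both`) and
#'   `merged` (an [InteractionNetwork-class]).
#' @export
overlapPpi <- function(litNet, ppiEdges, restrictToLitGenes = TRUE) {
  litGenes <- networkGenes(litNet)
  edges <- litNet@edges
  nodes <- litNet@nodes
  isGG <- vapply(seq_len(nrow(edges)), function(i) {
    all(c(edges$a[i], edges$b[i]) %in% litGenes)
  }, logical(1))
  litKeys <- pairKey(edges$a[isGG], edges$b[isGG])
  ppi <- ppiEdges
  if (restrictToLitGenes && nrow(ppi)) {
    ppi <- ppi[ppi$a %in% litGenes & ppi$b %in% litGenes, , drop = FALSE]
  }
  ppiKeys <- if (nrow(ppi)) pairKey(ppi$a, ppi$b) else character()
  bothKeys <- intersect(litKeys, ppiKeys)
  counts <- c(lit_only = length(setdiff(litKeys, ppiKeys)),
              ppi_only = length(setdiff(ppiKeys, litKeys)),
              both = length(bothKeys))
  # merged network: retag shared literature edges, append ppi-only edges
  mEdges <- edges
  mEvidence <- litNet@evidence
  if (nrow(mEdges)) {
    keys <- pairKey(mEdges$a, mEdges$b)
    mEdges$source_tag[isGG & keys %in% bothKeys] <- "both"
  }
  newKeys <- setdiff(ppiKeys, litKeys)
  if (length(newKeys)) {
    parts <- strsplit(newKeys, "||", fixed = TRUE)
    add <- data.frame(a = vapply(parts, `[`, character(1), 1),
                      b = vapply(parts, `[`, character(1), 2),
                      n_sentences = 0L, max_score = NA_real_,
                      source_tag = "ppi", stringsAsFactors = FALSE)
    mEdges <- rbind(mEdges, add)
    mEvidence <- c(mEvidence, rep(list(character()), nrow(add)))
    newGenes <- setdiff(unique(c(add$a, add$b)), nodes$id)
    if (length(newGenes)) {
      nodes <- rbind(nodes, data.frame(id = newGenes, ntype = "gene",
                                       stringsAsFactors = FALSE))
    }
  }
  ord <- order(mEdges$a, mEdges$b)
  mEdges <- mEdges[ord, , drop = FALSE]
  mEvidence <- mEvidence[ord]
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(mEdges) <- rownames(nodes) <- NULL
  merged <- new("InteractionNetwork", nodes = nodes, edges = mEdges,
                evidence = mEvidence)
  list(counts = counts, merged = merged)
}

#' Indirect-interaction hypotheses around an anchor edge
#'
#' Given an anchor pair (a, b) present in the merged network, proposes
#' candidate pairs (x, y) where x is a literature-only neighbor of a and y
#' a PPI-only neighbor of b (plus the symmetric orientation), yielding
#' x - a - b - y bridge paths; all four nodes distinct; deduplicated.
#'
#' @param merged merged [InteractionNetwork-class] from [overlapPpi()].
#' @param anchor character(2): the anchor gene pair.
#' @return data.frame with columns `x`, `anchor_a`, `anchor_b`, `y`,
#'   `rationale`.
#' @export
indirectHypotheses <- function(merged, anchor) {
  stopifnot(length(anchor) == 2L)
  a <- anchor[1]; b <- anchor[2]
  edges <- merged@edges
  keys <- pairKey(edges$a, edges$b)
  if (!(pairKey(a, b) %in% keys))
    stop("anchor edge ", a, "-", b, " not present in the merged network")
  neighborsBy <- function(node, tag) {
    sel <- (edges$a == node | edges$b == node) & edges$source_tag == tag
    setdiff(unique(c(edges$a[sel], edges$b[sel])), node)
  }
  out <- list()
  addHyp <- function(x, ha, hb, y) {
    if (length(unique(c(x, ha, hb, y))) != 4L) return()
    out[[length(out) + 1L]] <<- data.frame(
      x = x, anchor_a = ha, anchor_b = hb, y = y,
      rationale = sprintf(
        "%s interacts with %s (literature) and %s with %s (PPI); %s-%s bridge suggests %s may interact with %s",
        x, ha, y, hb, ha, hb, x, y),
      stringsAsFactors = FALSE)
  }
  for (x in neighborsBy(a, "literature"))
    for (y in neighborsBy(b, "ppi")) addHyp(x, a, b, y)
  for (x in neighborsBy(b, "literature"))
    for (y in neighborsBy(a, "ppi")) addHyp(x, b, a, y)
  if (!length(out)) {
    return(data.frame(x = character(), anchor_a = character(),
                      anchor_b = character(), y = character(),
                      rationale = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[!duplicated(res[, c("x", "anchor_a", "anchor_b", "y")]), ,
      drop = FALSE]
}
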