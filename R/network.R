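# Interaction-network assembly and interchange formats.

.nodeTypeOf <- function(etype) ifelse(etype == "gene", "gene", "vaccine")

#' Build an interaction network from scored candidate pairs
#'
#' Only positively scored records contribute. Repeated occurrences of an
#' unordered pair merge into one edge accumulating per-sentence evidence;
#' self-pairs are dropped. Generic vaccine mentions map to the single node
#' id `"vaccine"`; specific vaccines keep their ontology term id.
#'
#' @param scored scored candidate data.frame (see [scoreCandidates()]).
#' @param pairKinds which pair kinds to include
#'   (default both `gene_gene` and `gene_vaccine`).
#' @param sourceTag provenance tag stored on every edge.
#' @return an [InteractionNetwork-class].
#' @export
buildNetwork <- function(scored, pairKinds = c("gene_gene", "gene_vaccine"),
                         sourceTag = "literature") {
  emptyNodes <- data.frame(id = character(), ntype = character(),
                           stringsAsFactors = FALSE)
  emptyEdges <- data.frame(a = character(), b = character(),
                           n_sentences = integer(), max_score = numeric(),
                           source_tag = character(), stringsAsFactors = FALSE)
  if (is.null(scored) || !nrow(scored)) {
    return(new("InteractionNetwork", nodes = emptyNodes, edges = emptyEdges,
               evidence = list()))
  }
  rec <- scored[scored$is_positive & scored$pair_kind %in% pairKinds &
                scored$a_norm != scored$b_norm, , drop = FALSE]
  if (!nrow(rec)) {
    return(new("InteractionNetwork", nodes = emptyNodes, edges = emptyEdges,
               evidence = list()))
  }
  swap <- rec$a_norm > rec$b_norm
  a <- ifelse(swap, rec$b_norm, rec$a_norm)
  b <- ifelse(swap, rec$a_norm, rec$b_norm)
  atype <- .nodeTypeOf(ifelse(swap, rec$b_etype, rec$a_etype))
  btype <- .nodeTypeOf(ifelse(swap, rec$a_etype, rec$b_etype))
  key <- paste(a, b, sep = "||")
  ev <- paste0(rec$doc_id, "#", rec$sent_index)
  ord <- order(key)
  idx <- split(ord, key[ord])
  edges <- lapply(names(idx), function(k) {
    rows <- idx[[k]]
    data.frame(a = a[rows[1]], b = b[rows[1]],
               n_sentences = length(unique(ev[rows])),
               max_score = max(rec$score[rows]),
               source_tag = sourceTag, stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, edges)
  evidence <- lapply(names(idx), function(k) sort(unique(ev[idx[[k]]])))
  nodeTab <- unique(data.frame(id = c(a, b), ntype = c(atype, btype),
                               stringsAsFactors = FALSE))
  nodeTab <- nodeTab[order(nodeTab$id), , drop = FALSE]
  rownames(nodeTab) <- rownames(edges) <- NULL
  new("InteractionNetwork", nodes = nodeTab, edges = edges,
      evidence = evidence)
}

#' Build a sub-network restricted to a document subset
#'
#' Only evidence whose `doc_id` lies in `docIds` contributes.
#'
#' @param scored scored candidate data.frame.
#' @param docIds character vector of document ids.
#' @inheritParams buildNetwork
#' @return an [InteractionNetwork-class].
#' @export
subnetworkByCorpus <- function(scored,
                               docIds,
                               pairKinds = c("gene_gene", "gene_vaccine"),
                               sourceTag = "literature") {
  buildNetwork(scored[scored$doc_id %in% docIds, , drop = FALSE],
               pairKinds = pairKinds, sourceTag = sourceTag)
}

#' Construct a network directly from node and edge tables
#'
#' Mainly for tests and for merging routines; validates the simple-graph
#' invariants.
#'
#' @param nodes data.frame `id`, `ntype`.
#' @param edges data.frame `a`, `b`, `n_sentences`, `max_score`,
#'   `source_tag`.
#' @param evidence list of evidence keys parallel to `edges`.
#' @return an [InteractionNetwork-class].
#' @export
makeNetwork <- function(nodes, edges, evidence = NULL) {
  if (is.null(evidence)) {
    evidence <- lapply(seq_len(nrow(edges)), function(i)
      if (edges$n_sentences[i] > 0)
        paste0("synthetic#", seq_len(edges$n_sentences[i])) else character())
  }
  swap <- edges$a > edges$b
  tmp <- edges$a[swap]; edges$a[swap] <- edges$b[swap]; edges$b[swap] <- tmp
  new("InteractionNetwork", nodes = nodes, edges = edges,
      evidence = evidence)
}

.asIgraph <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(net@nodes), name = net@nodes$id,
                            ntype = net@nodes$ntype)
  if (nrow(net@edges)) {
    g <- igraph::add_edges(
      g, rbind(net@edges$a, net@edges$b),
      n_sentences = net@edges$n_sentences,
      max_score = net@edges$max_score,
      source_tag = net@edges$source_tag,
      evidence = vapply(net@evidence, paste, character(1), collapse = "|"))
  }
  g
}

#' Export an interaction network
#'
#' Formats: `sif` (rows `idA interacts idB`, tab-separated), `graphml`
#' (all node and edge attributes; re-importable with
#' [importGraphmlNetwork()]), `tsv` (edge list with attribute columns;
#' header-only when the network is empty).
#'
#' @param net an [InteractionNetwork-class].
#' @param path output file.
#' @param format `"graphml"`, `"sif"`, or `"tsv"`.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(.asIgraph(net), path, format = "graphml")
  } else if (format == "sif") {
    rows <- if (nrow(net@edges))
      paste(net@edges$a, "interacts", net@edges$b, sep = "\t")
    else character()
    writeLines(rows, path)
  } else {
    tab <- net@edges
    tab$evidence <- vapply(net@evidence, paste, character(1),
                           collapse = "|")
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Import a network from GraphML written by [exportNetwork()]
#' @param path GraphML file.
#' @return an [InteractionNetwork-class].
#' @export
importGraphmlNetwork <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(id = igraph::V(g)$name,
                      ntype = igraph::V(g)$ntype,
                      stringsAsFactors = FALSE)
  ne <- igraph::ecount(g)
  if (ne) {
    ends <- igraph::as_edgelist(g)
    edges <- data.frame(
      a = pmin(ends[, 1], ends[, 2]), b = pmax(ends[, 1], ends[, 2]),
      n_sentences = as.integer(igraph::E(g)$n_sentences),
      max_score = as.numeric(igraph::E(g)$max_score),
      source_tag = igraph::E(g)$source_tag, stringsAsFactors = FALSE)
    evidence <- lapply(igraph::E(g)$evidence, function(x)
      if (nzchar(x)) strsplit(x, "|", fixed = TRUE)[[1]] else character())
  } else {
    edges <- data.frame(a = character(), b = character(),
                        n_sentences = integer(), max_score = numeric(),
                        source_tag = character(), stringsAsFactors = FALSE)
    evidence <- list()
  }
  ord <- order(nodes$id)
  nodes <- nodes[ord, , drop = FALSE]
  if (nrow(edges)) {
    eord <- order(edges$a, edges$b)
    edges <- edges[eord, , drop = FALSE]
    evidence <- evidence[eord]
  }
  rownames(nodes) <- rownames(edges) <- NULL
  new("InteractionNetwork", nodes = nodes, edges = edges,
      evidence = evidence)
}

#' Structural equality of two networks
#'
#' Compares node and edge tables and evidence exactly, and `max_score`
#' within `scoreTol` (GraphML serializes doubles at about 15 significant
#' digits).
#'
#' @param x,y [InteractionNetwork-class] objects.
#' @param scoreTol absolute tolerance for `max_score`.
#' @return logical.
#' @export
networksEqual <- function(x, y, scoreTol = 1e-9) {
  nx <- x@nodes[order(x@nodes$id), ]; ny <- y@nodes[order(y@nodes$id), ]
  if (!identical(nx$id, ny$id) || !identical(nx$ntype, ny$ntype))
    return(FALSE)
  ex <- x@edges[order(x@edges$a, x@edges$b), , drop = FALSE]
  ey <- y@edges[order(y@edges$a, y@edges$b), , drop = FALSE]
  if (nrow(ex) != nrow(ey)) return(FALSE)
  if (!identical(ex$a, ey$a) || !identical(ex$b, ey$b)) return(FALSE)
  if (!identical(as.integer(ex$n_sentences), as.integer(ey$n_sentences)))
    return(FALSE)
  if (!identical(ex$source_tag, ey$source_tag)) return(FALSE)
  if (nrow(ex) && any(abs(ex$max_score - ey$max_score) > scoreTol))
    return(FALSE)
  evx <- x@evidence[order(x@edges$a, x@edges$b)]
  evy <- y@evidence[order(y@edges$a, y@edges$b)]
  identical(lapply(evx, sort), lapply(evy, sort))
}
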