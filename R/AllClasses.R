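#' @import methods
NULL

#' GeneLexicon: a dictionary of official gene symbols with synonyms
#'
#' Holds the lexicon entries (official symbol, full name, synonyms) plus a
#' precomputed lookup index from normalized surface forms to candidate
#' official symbols, and the set of raw (case-preserving) forms per key used
#' by the short-surface case-sensitivity rule.
#'
#' @slot entries data.frame with columns `symbol`, `name`, `synonyms`
#'   (pipe-separated string).
#' @slot index named list: normalized surface key -> character vector of
#'   official symbols.
#' @slot rawForms named list: normalized surface key -> character vector of
#'   original (un-lowercased) forms indexed under that key.
#' @slot maxTokens integer, maximum token count among indexed keys.
#' @exportClass GeneLexicon
setClass("GeneLexicon",
  representation(entries = "data.frame", index = "list",
                 rawForms = "list", maxTokens = "integer"),
  validity = function(object) {
    if (anyDuplicated(object@entries$symbol))
      return("official symbols must be unique")
    if (!all(c("symbol", "name", "synonyms") %in% colnames(object@entries)))
      return("entries must have columns symbol, name, synonyms")
    TRUE
  })

#' Ontology: an is_a hierarchy loaded from an OBO flat file
#'
#' @slot ids character vector of term ids.
#' @slot labels named character, term id -> primary label.
#' @slot synonyms named list, term id -> character vector of synonyms.
#' @slot parents named list, term id -> character vector of is_a parent ids.
#' @exportClass Ontology
setClass("Ontology",
  representation(ids = "character", labels = "character",
                 synonyms = "list", parents = "list"),
  validity = function(object) {
    if (anyDuplicated(object@ids)) return("term ids must be unique")
    allp <- unique(unlist(object@parents, use.names = FALSE))
    if (length(allp) && !all(allp %in% object@ids))
      return("is_a parent ids must all exist in the ontology")
    TRUE
  })

#' KernelModel: a trained edit-distance-kernel SVM
#'
#' Decision function: f(x) = sum_i coef_i * exp(-gamma * d(s_i, x)) + bias,
#' where d is token-level Levenshtein distance and s_i are the stored
#' support sequences. A path is called positive when f(x) > 0.
#'
#' @slot supportSequences list of character vectors (path token sequences).
#' @slot coefficients numeric, signed dual coefficients (alpha_i * y_i).
#' @slot bias numeric(1).
#' @slot gamma numeric(1), kernel decay rate (> 0).
#' @slot cost numeric(1), soft-margin cost C (> 0).
#' @slot psdRepaired logical(1), whether the training Gram matrix needed
#'   eigenvalue clipping.
#' @exportClass KernelModel
setClass("KernelModel",
  representation(supportSequences = "list", coefficients = "numeric",
                 bias = "numeric", gamma = "numeric", cost = "numeric",
                 psdRepaired = "logical"),
  validity = function(object) {
    if (length(object@supportSequences) != length(object@coefficients))
      return("one coefficient per support sequence required")
    if (object@gamma <= 0) return("gamma must be positive")
    if (object@cost <= 0) return("cost (C) must be positive")
    if (any(abs(object@coefficients) > object@cost + 1e-6))
      return("|dual coefficients| must not exceed C")
    TRUE
  })

#' InteractionNetwork: an undirected gene / gene-vaccine interaction graph
#'
#' Simple graph (no self-loops, no parallel edges). Edges carry the set of
#' evidence sentences ("doc_id#sent_index" strings), their count, the
#' maximum SVM confidence among supporting sentences, and a provenance tag
#' (`literature`, `ppi`, or `both`).
#'
#' @slot nodes data.frame with columns `id`, `ntype` (gene|vaccine).
#' @slot edges data.frame with columns `a`, `b`, `n_sentences`,
#'   `max_score`, `source_tag`; `a < b` lexicographically.
#' @slot evidence list of character vectors, parallel to edge rows.
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 evidence = "list"),
  validity = function(object) {
    e <- object@edges
    if (nrow(e)) {
      if (any(e$a == e$b)) return("self-loops are not allowed")
      if (anyDuplicated(pairKey(e$a, e$b)))
        return("parallel edges are not allowed")
      if (!all(c(e$a, e$b) %in% object@nodes$id))
        return("every edge endpoint must be a node")
      if (length(object@evidence) != nrow(e))
        return("evidence list must parallel the edge table")
      ns <- lengths(object@evidence)
      lit <- e$source_tag != "ppi"
      if (any(e$n_sentences != ns))
        return("n_sentences must equal the evidence count")
      if (any(lit & ns < 1L))
        return("literature edges need at least one evidence sentence")
    }
    if (anyDuplicated(object@nodes$id)) return("node ids must be unique")
    if (!all(object@nodes$ntype %in% c("gene", "vaccine")))
      return("node ntype must be gene or vaccine")
    TRUE
  })

setMethod("show", "GeneLexicon", function(object) {
  cat("GeneLexicon with", nrow(object@entries), "genes,",
      length(object@index), "indexed surface forms\n")
})

setMethod("show", "Ontology", function(object) {
  roots <- sum(lengths(object@parents) == 0L)
  cat("Ontology with", length(object@ids), "terms (", roots, "roots )\n")
})

setMethod("show", "KernelModel", function(object) {
  cat("KernelModel:", length(object@supportSequences), "support sequences,",
      sprintf("gamma=%g, C=%g, bias=%.4g", object@gamma, object@cost,
              object@bias),
      if (object@psdRepaired) "(Gram PSD-repaired)" else "", "\n")
})

setMethod("show", "InteractionNetwork", function(object) {
  nt <- table(factor(object@nodes$ntype, levels = c("gene", "vaccine")))
  cat("InteractionNetwork:", nrow(object@nodes), "nodes (",
      nt[["gene"]], "genes,", nt[["vaccine"]], "vaccines ),",
      nrow(object@edges), "edges\n")
})

#' Accessors for InteractionNetwork
#'
#' @param x an [InteractionNetwork-class] object.
#' @return `networkNodes` returns the node data.frame; `networkEdges` the
#'   edge data.frame; `edgeEvidence` the list of evidence sentence keys.
#' @export
networkNodes <- function(x) x@nodes

#' @rdname networkNodes
#' @export
networkEdges <- function(x) x@edges

#' @rdname networkNodes
#' @export
edgeEvidence <- function(x) x@evidence

#' Gene ids of a network
#' @param x an [InteractionNetwork-class] object.
#' @return character vector of gene node ids.
#' @export
networkGenes <- function(x) x@nodes$id[x@nodes$ntype == "gene"]
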