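# OBO 1.2 flat-file loading and is_a hierarchy queries.

#' Load an OBO 1.2 flat file
#'
#' Parses `[Term]` stanzas (`id`, `name`, `synonym`, `is_a`,
#' `is_obsolete`). Obsolete terms are skipped. Errors on is_a cycles and
#' dangling parent references.
#'
#' @param path OBO file.
#' @return an [Ontology-class] object.
#' @export
loadObo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ids <- character(); labels <- character()
  synonyms <- list(); parents <- list()
  cur <- NULL; inTerm <- FALSE
  flush <- function() {
    if (is.null(cur) || cur$obsolete || is.na(cur$id)) return()
    if (cur$id %in% ids) stop("duplicate term id: ", cur$id)
    ids <<- c(ids, cur$id)
    labels[[cur$id]] <<- cur$name
    synonyms[[cur$id]] <<- cur$syn
    parents[[cur$id]] <<- unique(cur$isa)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      cur <- list(id = NA_character_, name = NA_character_,
                  syn = character(), isa = character(), obsolete = FALSE)
      inTerm <- TRUE
      next
    }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; inTerm <- FALSE; next }
    if (!inTerm || !nzchar(ln)) next
    if (startsWith(ln, "id:")) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (startsWith(ln, "name:")) {
      cur$name <- trimws(sub("^name:", "", ln))
    } else if (startsWith(ln, "synonym:")) {
      m <- regmatches(ln, regexpr('"[^"]*"', ln))
      if (length(m)) cur$syn <- c(cur$syn, gsub('"', "", m))
    } else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      if (nzchar(tgt)) cur$isa <- c(cur$isa, tgt)
    } else if (grepl("^is_obsolete:\\s*true", ln)) {
      cur$obsolete <- TRUE
    }
  }
  flush()
  if (!length(ids)) stop("no [Term] stanzas found in ", path)
  # drop is_a links into obsolete/absent terms? No: dangling parent = error
  allp <- unique(unlist(parents, use.names = FALSE))
  missing <- setdiff(allp, ids)
  if (length(missing))
    stop("dangling is_a parent id(s): ", paste(missing, collapse = ", "))
  onto <- new("Ontology", ids = ids, labels = labels,
              synonyms = synonyms, parents = parents)
  .checkAcyclic(onto)
  onto
}

.checkAcyclic <- function(onto) {
  state <- setNames(integer(length(onto@ids)), onto@ids) # 0 new 1 open 2 done
  visit <- function(id) {
    if (state[[id]] == 1L) stop("is_a cycle detected at term ", id)
    if (state[[id]] == 2L) return()
    state[[id]] <<- 1L
    for (p in onto@parents[[id]]) visit(p)
    state[[id]] <<- 2L
  }
  for (id in onto@ids) visit(id)
  invisible(TRUE)
}

#' Transitive is_a ancestors of a term
#'
#' @param onto an [Ontology-class].
#' @param termId term id.
#' @return character vector of ancestor ids (reflexive-free transitive
#'   closure over is_a), in breadth-first discovery order.
#' @export
ontologyAncestors <- function(onto, termId) {
  if (!termId %in% onto@ids) stop("unknown term id: ", termId)
  seen <- character()
  frontier <- onto@parents[[termId]]
  while (length(frontier)) {
    newIds <- setdiff(frontier, seen)
    seen <- c(seen, newIds)
    frontier <- unique(unlist(onto@parents[newIds], use.names = FALSE))
  }
  seen
}

#' Descendants of a term (transitive closure over inverse is_a)
#' @inheritParams ontologyAncestors
#' @return character vector of descendant ids (excluding the term itself).
#' @export
ontologyDescendants <- function(onto, termId) {
  if (!termId %in% onto@ids) stop("unknown term id: ", termId)
  onto@ids[vapply(onto@ids, function(id)
    id != termId && termId %in% ontologyAncestors(onto, id), logical(1))]
}

#' Leaf terms under a root
#'
#' Descendants of `rootId` that have no children of their own. The root
#' itself is excluded even when childless.
#'
#' @param onto an [Ontology-class].
#' @param rootId the subtree root id.
#' @return character vector of leaf term ids.
#' @export
leafTerms <- function(onto, rootId) {
  desc <- ontologyDescendants(onto, rootId)
  hasChild <- unique(unlist(onto@parents, use.names = FALSE))
  setdiff(desc, hasChild)
}

#' Resolve the ontology term whose label equals `label`
#' @param onto an [Ontology-class].
#' @param label primary label to look up (exact, case-insensitive).
#' @return term id, or error if absent/ambiguous.
#' @export
termByLabel <- function(onto, label) {
  hit <- onto@ids[tolower(onto@labels[onto@ids]) == tolower(label)]
  if (length(hit) != 1L)
    stop("label ", label, " resolves to ", length(hit), " terms")
  hit
}
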