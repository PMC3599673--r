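# Independent brute-force oracles used to cross-check the implementations.

# word-level Levenshtein by exhaustive recursion (exponential; tiny inputs)
naiveEditDistance <- function(x, y) {
  if (!length(x)) return(length(y))
  if (!length(y)) return(length(x))
  sub <- naiveEditDistance(x[-1], y[-1]) + (x[1] != y[1])
  del <- naiveEditDistance(x[-1], y) + 1L
  ins <- naiveEditDistance(x, y[-1]) + 1L
  min(sub, del, ins)
}

# reachability over parent links by depth-first search
bruteAncestors <- function(parents, id) {
  seen <- character()
  visit <- function(x) {
    for (p in parents[[x]]) {
      if (!(p %in% seen)) {
        seen <<- c(seen, p)
        visit(p)
      }
    }
  }
  visit(id)
  sort(seen)
}

# adjacency list of an InteractionNetwork (test-local copy)
oracleAdj <- function(net) {
  e <- networkEdges(net)
  ids <- networkNodes(net)$id
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(e))) {
    adj[[e$a[i]]] <- c(adj[[e$a[i]]], e$b[i])
    adj[[e$b[i]]] <- c(adj[[e$b[i]]], e$a[i])
  }
  adj
}

oracleBfs <- function(adj, s) {
  d <- stats::setNames(rep(NA_integer_, length(adj)), names(adj))
  d[[s]] <- 0L
  q <- s
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (w in adj[[v]]) if (is.na(d[[w]])) { d[[w]] <- d[[v]] + 1L; q <- c(q, w) }
  }
  d
}

# all shortest paths s -> t by backtracking over BFS levels
allShortestPaths <- function(adj, d, t) {
  if (is.na(d[[t]])) return(list())
  if (d[[t]] == 0L) return(list(t))
  out <- list()
  for (u in adj[[t]]) {
    if (!is.na(d[[u]]) && d[[u]] == d[[t]] - 1L) {
      for (p in allShortestPaths(adj, d, u))
        out[[length(out) + 1L]] <- c(p, t)
    }
  }
  out
}

# betweenness by exhaustive shortest-path enumeration
bruteBetweenness <- function(net) {
  adj <- oracleAdj(net)
  ids <- names(adj)
  cb <- stats::setNames(numeric(length(ids)), ids)
  for (i in seq_along(ids)) {
    s <- ids[i]
    d <- oracleBfs(adj, s)
    for (j in seq_along(ids)) {
      if (j <= i) next
      t <- ids[j]
      paths <- allShortestPaths(adj, d, t)
      if (!length(paths)) next
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        for (v in interior) cb[[v]] <- cb[[v]] + 1 / length(paths)
      }
    }
  }
  cb
}

# dominant eigenvector of the dense adjacency via eigen()
denseEigenOracle <- function(net) {
  ids <- networkNodes(net)$id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- networkEdges(net)
  for (i in seq_len(nrow(e))) {
    A[e$a[i], e$b[i]] <- 1
    A[e$b[i], e$a[i]] <- 1
  }
  eg <- eigen(A, symmetric = TRUE)
  v <- eg$vectors[, which.max(eg$values)]
  v <- v * sign(sum(v))       # orient nonnegative
  stats::setNames(v / sqrt(sum(v^2)), ids)
}

# hypergeometric upper tail P(X >= k) by summing counts (no phyper)
chooseTail <- function(k, N, K, n) {
  js <- seq(max(k, 0L), min(K, n))
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# literal enumeration over all C(N, n) draws (tiny N only)
enumTail <- function(k, N, K, n) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # genes 1..K belong to the term
  mean(hits >= k)
}

# random simple undirected network on n nodes, edge prob p
randomTestNetwork <- function(n, p = 0.4, namePrefix = "g") {
  ids <- paste0(namePrefix, seq_len(n))
  pairs <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(pairs)) < p
  ne <- sum(keep)
  edges <- data.frame(a = pairs[1, keep], b = pairs[2, keep],
                      n_sentences = sample(1:3, ne, replace = TRUE),
                      max_score = round(stats::runif(ne), 6),
                      source_tag = rep("literature", ne),
                      stringsAsFactors = FALSE)
  makeNetwork(data.frame(id = ids, ntype = "gene",
                         stringsAsFactors = FALSE), edges)
}

randomConnectedNetwork <- function(n, extra = 0.3) {
  ids <- paste0("g", seq_len(n))
  edges <- list()
  for (i in seq_len(n - 1L)) {       # random spanning tree
    j <- sample.int(i, 1)
    edges[[i]] <- sort(c(ids[i + 1L], ids[j]))
  }
  pairs <- utils::combn(ids, 2)
  for (c_ in seq_len(ncol(pairs))) {
    if (stats::runif(1) < extra) {
      edges[[length(edges) + 1L]] <- c(pairs[1, c_], pairs[2, c_])
    }
  }
  m <- unique(do.call(rbind, edges))
  edges <- data.frame(a = m[, 1], b = m[, 2], n_sentences = 1L,
                      max_score = 1, source_tag = "literature",
                      stringsAsFactors = FALSE)
  makeNetwork(data.frame(id = ids, ntype = "gene",
                         stringsAsFactors = FALSE), edges)
}

# random ontology DAG as an Ontology object (ids t1..tn, edges i -> j<i)
randomDagOntology <- function(n, p = 0.35) {
  ids <- paste0("t", seq_len(n))
  parents <- stats::setNames(vector("list", n), ids)
  for (i in seq_len(n)) parents[[i]] <- character()
  for (i in seq(2L, length.out = max(0L, n - 1L))) {
    for (j in seq_len(i - 1L)) {
      if (stats::runif(1) < p) parents[[ids[i]]] <- c(parents[[ids[i]]], ids[j])
    }
  }
  methods::new("Ontology", ids = ids,
               labels = stats::setNames(paste("term", ids), ids),
               synonyms = stats::setNames(rep(list(character()), n), ids),
               parents = parents)
}

# random token sequences over a small vocabulary
randomTokenSeq <- function(maxLen = 6L, vocab = c("a", "b", "c", "x", "nsubj<", "dobj>")) {
  n <- sample.int(maxLen + 1L, 1L) - 1L
  if (!n) return(character())
  sample(vocab, n, replace = TRUE)
}
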