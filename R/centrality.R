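# Centrality metrics, ranking, and two-network top-k comparison.

# Adjacency list over all nodes of the network (undirected, unweighted).
.adjList <- function(net) {
  ids <- net@nodes$id
  adj <- setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(net@edges))) {
    a <- net@edges$a[i]; b <- net@edges$b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

.bfsDistances <- function(adj, from) {
  d <- setNames(rep(NA_integer_, length(adj)), names(adj))
  d[[from]] <- 0L
  frontier <- from
  while (length(frontier)) {
    nxt <- character()
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (is.na(d[[v]])) {
          d[[v]] <- d[[u]] + 1L
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  d
}

#' Degree centrality
#' @param net an [InteractionNetwork-class].
#' @return named numeric vector of raw degree counts per node.
#' @export
degreeCentrality <- function(net) {
  deg <- setNames(numeric(nrow(net@nodes)), net@nodes$id)
  for (i in seq_len(nrow(net@edges))) {
    deg[net@edges$a[i]] <- deg[net@edges$a[i]] + 1
    deg[net@edges$b[i]] <- deg[net@edges$b[i]] + 1
  }
  deg
}

#' Eigenvector centrality
#'
#' Power iteration from a uniform positive start, L2-normalized each step;
#' converged when successive iterates differ by less than `tol` in maximum
#' absolute difference. Iteration runs on A + I (same eigenvectors as the
#' adjacency A, with the spectrum shifted so the dominant eigenvector is
#' unique on connected graphs and the iteration cannot oscillate on
#' bipartite graphs).
#'
#' @param net an [InteractionNetwork-class] with at least one edge.
#' @param tol convergence tolerance.
#' @param maxIter iteration cap; exceeding it is an error reporting the
#'   last iterate gap.
#' @return named numeric vector, L2-normalized, nonnegative.
#' @export
eigenvectorCentrality <- function(net, tol = 1e-10, maxIter = 100000L) {
  if (!nrow(net@edges)) stop("eigenvector centrality needs at least one edge")
  ids <- net@nodes$id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(nrow(net@edges))) {
    A[net@edges$a[i], net@edges$b[i]] <- 1
    A[net@edges$b[i], net@edges$a[i]] <- 1
  }
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(maxIter)) {
    xn <- as.numeric(A %*% x) + x   # (A + I) x
    xn <- xn / sqrt(sum(xn^2))
    gap <- max(abs(xn - x))
    x <- xn
    if (gap < tol) return(setNames(pmax(x, 0), ids))
  }
  stop(sprintf(
    "eigenvector centrality did not converge in %d iterations (gap %.3e)",
    maxIter, gap))
}

#' Closeness centrality with component-size correction
#'
#' Within a connected component of size `n_c`, a node scores
#' `(n_c - 1) / sum(d)` scaled by `(n_c - 1) / (N - 1)` (Wasserman-Faust
#' correction for disconnected graphs). Isolated nodes score 0.
#'
#' @param net an [InteractionNetwork-class].
#' @return named numeric vector.
#' @export
closenessCentrality <- function(net) {
  adj <- .adjList(net)
  N <- length(adj)
  out <- setNames(numeric(N), names(adj))
  if (N <= 1L) return(out)
  for (v in names(adj)) {
    d <- .bfsDistances(adj, v)
    reach <- d[!is.na(d)]
    nc <- length(reach)           # component size including v
    if (nc <= 1L) next
    total <- sum(reach)
    out[[v]] <- ((nc - 1) / total) * ((nc - 1) / (N - 1))
  }
  out
}

#' Betweenness centrality (Brandes accumulation)
#'
#' Unnormalized shortest-path betweenness on the undirected, unweighted
#' graph; endpoints excluded; each unordered pair counted once.
#'
#' @param net an [InteractionNetwork-class].
#' @return named numeric vector.
#' @export
betweennessCentrality <- function(net) {
  adj <- .adjList(net)
  ids <- names(adj)
  cb <- setNames(numeric(length(ids)), ids)
  for (s in ids) {
    stack <- character()
    pred <- setNames(vector("list", length(ids)), ids)
    sigma <- setNames(numeric(length(ids)), ids); sigma[[s]] <- 1
    d <- setNames(rep(-1L, length(ids)), ids); d[[s]] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      stack <- c(stack, v)
      for (w in adj[[v]]) {
        if (d[[w]] < 0L) {
          queue <- c(queue, w)
          d[[w]] <- d[[v]] + 1L
        }
        if (d[[w]] == d[[v]] + 1L) {
          sigma[[w]] <- sigma[[w]] + sigma[[v]]
          pred[[w]] <- c(pred[[w]], v)
        }
      }
    }
    delta <- setNames(numeric(length(ids)), ids)
    for (w in rev(stack)) {
      for (v in pred[[w]]) {
        delta[[v]] <- delta[[v]] +
          (sigma[[v]] / sigma[[w]]) * (1 + delta[[w]])
      }
      if (w != s) cb[[w]] <- cb[[w]] + delta[[w]]
    }
  }
  cb / 2  # undirected: each pair visited from both endpoints
}

#' Centrality report for a network
#'
#' Computes all four centralities on the full graph. Ranks are assigned by
#' descending score with ties broken by node id ascending (a deterministic
#' permutation); by default only gene nodes are ranked, mirroring gene
#' prioritization, with vaccine nodes reported unranked.
#'
#' @param net an [InteractionNetwork-class].
#' @param rankNodes `"gene"` (default) or `"all"`.
#' @return data.frame with per-node scores (`degree`, `eigenvector`,
#'   `closeness`, `betweenness`) and ranks (`rank_<metric>`; `NA` for
#'   unranked nodes).
#' @export
centralityReport <- function(net, rankNodes = c("gene", "all")) {
  rankNodes <- match.arg(rankNodes)
  scores <- list(degree = degreeCentrality(net),
                 eigenvector = eigenvectorCentrality(net),
                 closeness = closenessCentrality(net),
                 betweenness = betweennessCentrality(net))
  tab <- data.frame(node = net@nodes$id, ntype = net@nodes$ntype,
                    stringsAsFactors = FALSE)
  rankable <- if (rankNodes == "gene") tab$ntype == "gene"
              else rep(TRUE, nrow(tab))
  for (m in names(scores)) {
    tab[[m]] <- as.numeric(scores[[m]][tab$node])
    rk <- rep(NA_integer_, nrow(tab))
    sub <- which(rankable)
    ord <- sub[order(-tab[[m]][sub], tab$node[sub])]
    rk[ord] <- seq_along(ord)
    tab[[paste0("rank_", m)]] <- rk
  }
  tab
}

#' Top-k nodes by one centrality metric
#'
#' @param report a [centralityReport()] data.frame.
#' @param metric one of `degree`, `eigenvector`, `closeness`,
#'   `betweenness`.
#' @param k number of nodes (>= 1); fewer returned when the network is
#'   smaller.
#' @return character vector of node ids in rank order.
#' @export
topK <- function(report, metric = c("degree", "eigenvector", "closeness",
                                    "betweenness"), k = 10) {
  metric <- match.arg(metric)
  if (k < 1) stop("k must be >= 1")
  rk <- report[[paste0("rank_", metric)]]
  sel <- report$node[!is.na(rk) & rk <= k]
  sel[order(rk[!is.na(rk) & rk <= k])]
}

#' Nodes ranked among the top k by at least one centrality measure
#' @inheritParams topK
#' @return character vector of node ids (sorted).
#' @export
topKAny <- function(report, k = 10) {
  sort(unique(unlist(lapply(
    c("degree", "eigenvector", "closeness", "betweenness"),
    function(m) topK(report, m, k)))))
}

#' Compare the most central genes of two networks
#'
#' Membership = "ranked among the top k by at least one centrality measure"
#' in the respective network. Returns the genes central in both networks
#' and those central in only one.
#'
#' @param reportA,reportB [centralityReport()] data.frames.
#' @param k rank cutoff (same for both networks).
#' @return list with sorted character vectors `both`, `a_only`, `b_only`,
#'   and the `k` used.
#' @export
compareTopSets <- function(reportA, reportB, k = 10) {
  ta <- topKAny(reportA, k)
  tb <- topKAny(reportB, k)
  list(both = intersect(ta, tb),
       a_only = setdiff(ta, tb),
       b_only = setdiff(tb, ta),
       k = k)
}

#' Two-network rank table for the most central genes
#'
#' One row per gene that is top-k in either network; metric-wise ranks in
#' each network, `"---"` beyond k.
#'
#' @inheritParams compareTopSets
#' @return data.frame with columns `gene` and
#'   `<net>_<D|E|B|C>` rank strings.
#' @export
comparisonTable <- function(reportA, reportB, k = 10) {
  genes <- sort(union(topKAny(reportA, k), topKAny(reportB, k)))
  metrics <- c(D = "degree", E = "eigenvector", B = "betweenness",
               C = "closeness")
  cell <- function(report, gene, metric) {
    rk <- report[[paste0("rank_", metric)]][report$node == gene]
    if (!length(rk) || is.na(rk) || rk > k) "---" else as.character(rk)
  }
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (tag in names(metrics)) {
    out[[paste0("a_", tag)]] <- vapply(genes, cell, character(1),
                                       report = reportA,
                                       metric = metrics[[tag]])
    out[[paste0("b_", tag)]] <- vapply(genes, cell, character(1),
                                       report = reportB,
                                       metric = metrics[[tag]])
  }
  out
}
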