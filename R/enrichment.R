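# Gene-set over-representation analysis (Fisher / EASE, BH correction).

#' Load a gene-set annotation database from GMT
#'
#' GMT rows: term id, description, then member genes. Duplicate genes
#' within a row are collapsed. The background defaults to the union of all
#' term genes; an explicit background must cover every annotated gene.
#'
#' @param path GMT file.
#' @param background optional character vector of background genes.
#' @return list with `terms` (named list of gene sets), `names` (named
#'   character of term descriptions), `background` (character vector).
#' @export
loadGmt <- function(path, background = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  terms <- list(); descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT row ", i, " has fewer than 3 fields")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT row ", i, " has an empty gene set")
    if (f[1] %in% names(terms)) stop("duplicate GMT term: ", f[1])
    terms[[f[1]]] <- genes
    descs[[f[1]]] <- f[2]
  }
  union_ <- sort(unique(unlist(terms, use.names = FALSE)))
  if (is.null(background)) {
    background <- union_
  } else {
    missing <- setdiff(union_, background)
    if (length(missing))
      stop("explicit background misses annotated gene(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    background <- unique(background)
  }
  list(terms = terms, names = descs, background = background)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (sort ascending, `p_(i) * m / i`, enforce
#' monotonicity from the largest down, cap at 1), returned in input order.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis of a gene set
#'
#' For each annotation term with query overlap `k >= minOverlap` (default 2),
#' computes the upper-tail hypergeometric probability `P(X >= k)` given
#' background size `N`, term size `K`, and query size `n`. The `ease`
#' method (the default; DAVID's conservative "modified Fisher's exact
#' test") replaces `k` by `max(k - 1, 0)` before taking the tail.
#' Benjamini-Hochberg correction is applied across all tested terms.
#'
#' @param query character vector of genes.
#' @param db annotation database from [loadGmt()].
#' @param method `"ease"` or `"fisher"`.
#' @param alpha significance level for the BH-adjusted p-value.
#' @param minOverlap minimum query-term overlap for a term to be tested.
#' @return data.frame sorted by `p_adj` ascending with columns `term`,
#'   `term_name`, `k`, `K`, `n`, `N`, `p_raw`, `p_adj`, `significant`.
#' @export
enrich <- function(query, db, method = c("ease", "fisher"), alpha = 0.05,
                   minOverlap = 2L) {
  method <- match.arg(method)
  q <- intersect(unique(query), db$background)
  if (!length(q))
    stop("query has no genes in the annotation background")
  N <- length(db$background)
  n <- length(q)
  rows <- list()
  for (term in names(db$terms)) {
    tg <- db$terms[[term]]
    K <- length(tg)
    k <- length(intersect(q, tg))
    if (k < minOverlap) next
    keff <- if (method == "ease") max(k - 1L, 0L) else k
    p <- stats::phyper(keff - 1L, K, N - K, n, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      term = term, term_name = db$names[[term]], k = k, K = K, n = n,
      N = N, p_raw = p, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(term = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_raw = numeric(), p_adj = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bhAdjust(out$p_raw)
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p_adj, out$p_raw, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
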