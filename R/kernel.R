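# Edit-distance kernel over dependency-path token sequences.

#' Token-level Levenshtein distance
#'
#' Word-level edit distance with unit insert/delete/substitute costs over
#' whole tokens. Empty sequences are allowed.
#'
#' @param x,y character vectors (token sequences).
#' @return nonnegative integer distance.
#' @export
editDistance <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L) return(ny)
  if (ny == 0L) return(nx)
  prev <- 0:ny
  for (i in seq_len(nx)) {
    cur <- integer(ny + 1L)
    cur[1] <- i
    for (j in seq_len(ny)) {
      cost <- if (x[i] == y[j]) 0L else 1L
      cur[j + 1L] <- min(prev[j + 1L] + 1L,  # delete
                         cur[j] + 1L,        # insert
                         prev[j] + cost)     # substitute
    }
    prev <- cur
  }
  prev[ny + 1L]
}

#' Edit-distance kernel between two path sequences
#'
#' `k(x, y) = exp(-gamma * d(x, y))` with `d` the token-level Levenshtein
#' distance: symmetric, bounded in (0, 1], and `k(x, x) = 1`.
#'
#' @param x,y token sequences.
#' @param gamma positive decay rate.
#' @return kernel value in (0, 1].
#' @export
pathKernel <- function(x, y, gamma = 0.25) {
  if (gamma <= 0) stop("gamma must be positive")
  exp(-gamma * editDistance(x, y))
}

#' Gram matrix over path sequences, with PSD repair
#'
#' Edit-distance kernels are not guaranteed positive semidefinite. When the
#' smallest eigenvalue falls below `-tol`, negative eigenvalues are clipped
#' to zero and the matrix reconstituted; the `psd_repaired` attribute
#' records whether this happened.
#'
#' @param paths list of token sequences (length >= 1).
#' @param gamma positive decay rate.
#' @param tol eigenvalue tolerance.
#' @return symmetric numeric matrix with attribute `psd_repaired`.
#' @export
gramMatrix <- function(paths, gamma = 0.25, tol = 1e-9) {
  if (gamma <= 0) stop("gamma must be positive")
  n <- length(paths)
  if (n < 1L) stop("at least one path required")
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      if (j < i) {
        D[i, j] <- D[j, i] <- editDistance(paths[[i]], paths[[j]])
      }
    }
  }
  K <- exp(-gamma * D)
  repaired <- FALSE
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -tol) {
    vals <- pmax(eg$values, 0)
    K <- eg$vectors %*% (vals * t(eg$vectors))
    K <- (K + t(K)) / 2
    repaired <- TRUE
  }
  attr(K, "psd_repaired") <- repaired
  K
}
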