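# Kernel SVM over dependency paths: training, scoring, model I/O.

.parsePathColumn <- function(x) strsplit(x, " ", fixed = TRUE)

#' Read labeled dependency paths from TSV
#'
#' Expects columns `path` (sequence tokens joined by spaces) and `label`
#' (+1 / -1).
#'
#' @param path TSV file.
#' @return data.frame with columns `path` (character), `label` (integer).
#' @export
readLabeledPaths <- function(path) {
  d <- utils::read.delim(path, colClasses = "character", quote = "",
                         na.strings = NULL)
  if (!all(c("path", "label") %in% colnames(d)))
    stop("labeled-path TSV needs columns path/label")
  d$label <- as.integer(d$label)
  if (!all(d$label %in% c(-1L, 1L))) stop("labels must be +1 or -1")
  if (any(!nzchar(d$path))) stop("empty path sequence in ", path)
  d
}

#' Train the edit-distance-kernel SVM
#'
#' Solves the soft-margin dual on the (PSD-repaired) Gram matrix of the
#' training sequences via a C-classification SVM with a precomputed kernel
#' matrix. The stored decision function is
#' `f(x) = sum_i coef_i * k(s_i, x) + bias`, oriented so that positive
#' training labels receive positive decision values. Test-time scoring uses
#' the raw (unrepaired) kernel.
#'
#' @param sequences list of token sequences, or character vector of
#'   space-joined sequences.
#' @param labels integer vector of +1/-1 labels.
#' @param C soft-margin cost (> 0).
#' @param gamma kernel decay rate (> 0).
#' @param seed integer seed (training is deterministic given seed and data
#'   order).
#' @return a [KernelModel-class].
#' @export
trainPathSVM <- function(sequences, labels, C = 1.0, gamma = 0.25,
                         seed = 42L) {
  if (is.character(sequences)) sequences <- .parsePathColumn(sequences)
  if (length(sequences) != length(labels))
    stop("one label per sequence required")
  if (any(lengths(sequences) == 0L)) stop("sequences must be nonempty")
  labels <- as.integer(labels)
  if (!all(labels %in% c(-1L, 1L))) stop("labels must be +1 or -1")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the training data")
  if (C <= 0) stop("C must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  set.seed(seed)
  K <- gramMatrix(sequences, gamma)
  y <- factor(labels, levels = c(-1L, 1L))
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc",
                       C = C)
  ai <- kernlab::alphaindex(fit)[[1]]
  cf <- as.numeric(kernlab::coef(fit)[[1]])
  b0 <- kernlab::b(fit)
  # kernlab decision: f = K[, SV] %*% coef - b; orient so +1 labels score
  # positive (kernlab's internal class orientation is data-order dependent)
  dec <- as.numeric(K[, ai, drop = FALSE] %*% cf) - b0
  agree <- mean(sign(dec) == sign(labels + 0.0), na.rm = TRUE)
  s <- if (agree >= 0.5) 1 else -1
  new("KernelModel",
      supportSequences = sequences[ai],
      coefficients = s * cf,
      bias = -s * b0,
      gamma = gamma, cost = C,
      psdRepaired = isTRUE(attr(K, "psd_repaired")))
}

#' Decision values for path sequences
#'
#' @param model a [KernelModel-class].
#' @param sequences list of token sequences or character vector of
#'   space-joined sequences.
#' @param threshold decision threshold; pairs with `score > threshold` are
#'   positive. Defaults to 0 (positive confidence scores define edges).
#' @return data.frame with columns `score`, `is_positive`.
#' @export
scorePaths <- function(model, sequences, threshold = 0) {
  if (is.character(sequences)) sequences <- .parsePathColumn(sequences)
  score <- vapply(sequences, function(x) {
    k <- vapply(model@supportSequences,
                function(s) exp(-model@gamma * editDistance(s, x)),
                numeric(1))
    sum(model@coefficients * k) + model@bias
  }, numeric(1))
  data.frame(score = score, is_positive = score > threshold)
}

#' Score candidate pairs
#'
#' @param model a [KernelModel-class].
#' @param candidates candidate data.frame with a `path` column
#'   (see [extractPaths()]).
#' @inheritParams scorePaths
#' @return `candidates` with `score` and `is_positive` columns appended.
#' @export
scoreCandidates <- function(model, candidates, threshold = 0) {
  sc <- scorePaths(model, candidates$path, threshold)
  candidates$score <- sc$score
  candidates$is_positive <- sc$is_positive
  candidates
}

#' k-fold cross-validated F1 of the path classifier
#'
#' Pools held-out predictions over all folds and reports precision, recall
#' and F1 of the positive class.
#'
#' @param sequences,labels training data as in [trainPathSVM()].
#' @param folds number of folds.
#' @param C,gamma hyperparameters.
#' @param seed integer seed controlling the fold assignment.
#' @return named numeric vector: `precision`, `recall`, `f1`.
#' @export
crossValidatePathSVM <- function(sequences, labels, folds = 10, C = 1.0,
                                 gamma = 0.25, seed = 42L) {
  if (is.character(sequences)) sequences <- .parsePathColumn(sequences)
  labels <- as.integer(labels)
  n <- length(sequences)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  pred <- integer(n)
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (!length(te)) next
    m <- trainPathSVM(sequences[tr], labels[tr], C = C, gamma = gamma,
                      seed = seed)
    pred[te] <- ifelse(scorePaths(m, sequences[te])$is_positive, 1L, -1L)
  }
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == -1L)
  fn <- sum(pred == -1L & labels == 1L)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Write a kernel model to a portable text file
#'
#' JSON layout: `gamma`, `C`, `bias`, `psd_repaired`, and per-support
#' `coefficient` + space-joined `sequence`.
#'
#' @param model a [KernelModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeKernelModel <- function(model, path) {
  obj <- list(
    gamma = model@gamma, C = model@cost, bias = model@bias,
    psd_repaired = model@psdRepaired,
    coefficients = model@coefficients,
    sequences = vapply(model@supportSequences, paste, character(1),
                       collapse = " "))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a kernel model written by [writeKernelModel()]
#' @param path model file.
#' @return a [KernelModel-class].
#' @export
readKernelModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("KernelModel",
      supportSequences = .parsePathColumn(obj$sequences),
      coefficients = as.numeric(obj$coefficients),
      bias = as.numeric(obj$bias), gamma = as.numeric(obj$gamma),
      cost = as.numeric(obj$C), psdRepaired = isTRUE(obj$psd_repaired))
}
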