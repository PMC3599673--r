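test_that("GMT loading builds term sets and a union background", {
  f <- writeTempLines(c("T1\tfirst set\tA\tB\tC",
                        "T2\tsecond set\tB\tC\tD\tD"), ".gmt")
  db <- loadGmt(f)
  expect_length(db$terms, 2L)
  expect_setequal(db$terms$T2, c("B", "C", "D"))  # duplicate collapsed
  expect_setequal(db$background, c("A", "B", "C", "D"))

  short <- writeTempLines("T1\tonly two fields", ".gmt")
  expect_error(loadGmt(short), "fewer than 3")

  f2 <- writeTempLines("T1\tset\tA\tB", ".gmt")
  expect_error(loadGmt(f2, background = c("A")), "background")
  db2 <- loadGmt(f2, background = c("A", "B", "Z"))
  expect_length(db2$background, 3L)
})

test_that("the hypergeometric tail matches the exact enumeration case", {
  genes <- paste0("G", 1:20)
  f <- writeTempLines(c(
    paste(c("T1", "term", genes[1:5]), collapse = "\t"),
    paste(c("BG", "rest", genes), collapse = "\t")), ".gmt")
  db <- loadGmt(f)
  res <- enrich(genes[1:5], db, method = "fisher")
  # query of exactly the 5 term genes out of N=20: P(X >= 5) = 1/C(20,5)
  expect_equal(res$p_raw[res$term == "T1"], 1 / choose(20, 5),
               tolerance = 1e-12)
})

test_that("tail probabilities match count-sum and literal draw enumeration", {
  for (N in c(8L, 12L, 20L, 30L)) {
    for (K in unique(c(2L, N %/% 3L, N %/% 2L))) {
      for (n in unique(c(2L, N %/% 4L, N %/% 2L))) {
        for (k in 0:min(K, n)) {
          mine <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
          expect_equal(mine, chooseTail(k, N, K, n), tolerance = 1e-12)
          if (N <= 12L)
            expect_equal(mine, enumTail(k, N, K, n), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("terms with overlap below the minimum are skipped", {
  f <- writeTempLines(c("T1\ta\tA\tB\tC", "T2\tb\tD\tE\tF",
                        "T3\tc\tA\tD\tE"), ".gmt")
  db <- loadGmt(f)
  res <- enrich(c("A", "B"), db)
  expect_true("T1" %in% res$term)
  expect_false("T2" %in% res$term)  # k = 0
  expect_false("T3" %in% res$term)  # k = 1 < 2
})

test_that("EASE is uniformly more conservative than Fisher", {
  set.seed(505)
  genes <- paste0("G", 1:40)
  rows <- vapply(1:8, function(i)
    paste(c(paste0("T", i), "set",
            sample(genes, sample(5:15, 1))), collapse = "\t"),
    character(1))
  db <- loadGmt(writeTempLines(rows, ".gmt"))
  q <- sample(db$background, 12)
  fisher <- enrich(q, db, method = "fisher", minOverlap = 2)
  ease <- enrich(q, db, method = "ease", minOverlap = 2)
  shared <- intersect(fisher$term, ease$term)
  for (tm in shared) {
    expect_gte(ease$p_raw[ease$term == tm],
               fisher$p_raw[fisher$term == tm])
  }
})

test_that("querying a full term yields its minimal possible p", {
  genes <- paste0("G", 1:15)
  f <- writeTempLines(c(
    paste(c("T1", "t", genes[1:6]), collapse = "\t"),
    paste(c("BG", "b", genes), collapse = "\t")), ".gmt")
  db <- loadGmt(f)
  pFull <- enrich(genes[1:6], db, method = "fisher")$p_raw[1]
  pPart <- enrich(genes[2:7], db, method = "fisher")
  expect_lte(pFull, pPart$p_raw[pPart$term == "T1"])
  expect_error(enrich("NOT_THERE", db), "background")
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(0.04, 5)), rep(0.04, 5))
  # hand-applied: sorted p * m / i with monotone pass
  p <- c(0.03, 0.002, 0.04, 0.0001)
  byHand <- function(p) {
    m <- length(p); o <- order(p)
    adj <- p[o] * m / seq_len(m)
    for (i in seq(m - 1L, 1L)) adj[i] <- min(adj[i], adj[i + 1L])
    pmin(adj, 1)[order(o)]
  }
  expect_equal(bhAdjust(p), byHand(p))
  expect_error(bhAdjust(c(0.1, 1.2)), "0, 1")
  expect_error(bhAdjust(c(-0.1)), "0, 1")
})

test_that("BH is permutation-invariant and never below the raw p", {
  set.seed(606)
  for (trial in 1:20) {
    p <- stats::runif(sample(1:12, 1))
    adj <- bhAdjust(p)
    expect_true(all(adj >= p - 1e-12))
    perm <- sample(seq_along(p))
    expect_equal(bhAdjust(p[perm]), adj[perm])
  }
})

test_that("enrichment results are sorted and flagged at alpha", {
  genes <- paste0("G", 1:30)
  f <- writeTempLines(c(
    paste(c("T1", "tight", genes[1:5]), collapse = "\t"),
    paste(c("T2", "loose", genes[1:20]), collapse = "\t"),
    paste(c("BG", "bg", genes), collapse = "\t")), ".gmt")
  db <- loadGmt(f)
  res <- enrich(genes[1:5], db, method = "fisher", alpha = 0.05)
  expect_equal(res$p_adj, sort(res$p_adj))
  expect_identical(res$significant, res$p_adj < 0.05)
  expect_true(all(res$p_adj >= res$p_raw - 1e-12))
  expect_true(all(res$k <= pmin(res$n, res$K)))
})
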