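ppiLex <- function() {
  buildGeneLexicon(data.frame(
    symbol = c("A1", "B1", "C1", "D1", "TNF", "TNFRSF1A", "IL6", "IL1B",
               "MAPK1", "TRAF1", "CHUK", "HSP90AA1"),
    name = paste("gene", 1:12),
    synonyms = "", stringsAsFactors = FALSE))
}

test_that("PPI reading normalizes, deduplicates and drops self-pairs", {
  lex <- ppiLex()
  f <- writeTempLines(c("A1\tB1", "B1\tA1", "C1\tC1", "A1\tNOPE_GENE"),
                      ".tsv")
  edges <- readPpi(f, lex)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$a, "A1")
  expect_equal(attr(edges, "n_unmapped"), 1L)
  one <- writeTempLines("A1", ".tsv")
  expect_error(readPpi(one, lex), "2 columns")
})

litFixture <- function() {
  makeNetwork(
    data.frame(id = c("A1", "B1", "C1"), ntype = "gene",
               stringsAsFactors = FALSE),
    data.frame(a = c("A1", "A1"), b = c("B1", "C1"), n_sentences = 1L,
               max_score = 1, source_tag = "literature",
               stringsAsFactors = FALSE))
}

test_that("overlap counts follow the restricted set algebra", {
  lit <- litFixture()
  ppi <- data.frame(a = c("A1", "B1"), b = c("B1", "D1"),
                    stringsAsFactors = FALSE)
  ov <- overlapPpi(lit, ppi, restrictToLitGenes = TRUE)
  # B1-D1 drops (D1 outside literature genes): counts (lit_only, ppi_only, both)
  expect_equal(unname(ov$counts), c(1L, 0L, 1L))
  tags <- networkEdges(ov$merged)$source_tag
  expect_setequal(tags, c("both", "literature"))

  unrestricted <- overlapPpi(lit, ppi, restrictToLitGenes = FALSE)
  expect_equal(unname(unrestricted$counts), c(1L, 1L, 1L))
  expect_true("D1" %in% networkNodes(unrestricted$merged)$id)
})

test_that("identical and disjoint edge sets give all-both and zero-both", {
  lit <- litFixture()
  same <- data.frame(a = c("A1", "A1"), b = c("B1", "C1"),
                     stringsAsFactors = FALSE)
  ov <- overlapPpi(lit, same)
  expect_equal(unname(ov$counts), c(0L, 0L, 2L))
  disj <- data.frame(a = "B1", b = "C1", stringsAsFactors = FALSE)
  ov2 <- overlapPpi(lit, disj)
  expect_equal(ov2$counts[["both"]], 0L)
  expect_equal(ov2$counts[["ppi_only"]], 1L)
})

test_that("tags partition the merged edges and counts add up", {
  set.seed(808)
  genes <- paste0("G", 1:10)
  litEdges <- unique(t(replicate(8, sort(sample(genes, 2)))))
  lit <- makeNetwork(
    data.frame(id = genes, ntype = "gene", stringsAsFactors = FALSE),
    data.frame(a = litEdges[, 1], b = litEdges[, 2], n_sentences = 1L,
               max_score = 1, source_tag = "literature",
               stringsAsFactors = FALSE))
  ppiEdges <- unique(t(replicate(8, sort(sample(genes, 2)))))
  ppi <- data.frame(a = ppiEdges[, 1], b = ppiEdges[, 2],
                    stringsAsFactors = FALSE)
  ov <- overlapPpi(lit, ppi)
  e <- networkEdges(ov$merged)
  expect_equal(sum(e$source_tag == "both"), unname(ov$counts[["both"]]))
  expect_equal(sum(e$source_tag == "literature"),
               unname(ov$counts[["lit_only"]]))
  expect_equal(sum(e$source_tag == "ppi"), unname(ov$counts[["ppi_only"]]))
  expect_equal(unname(ov$counts[["both"]] + ov$counts[["lit_only"]]),
               nrow(networkEdges(lit)))
  # swapping inputs swaps the exclusive counts
  lit2 <- makeNetwork(
    data.frame(id = genes, ntype = "gene", stringsAsFactors = FALSE),
    data.frame(a = ppiEdges[, 1], b = ppiEdges[, 2], n_sentences = 1L,
               max_score = 1, source_tag = "literature",
               stringsAsFactors = FALSE))
  ov2 <- overlapPpi(lit2, data.frame(a = litEdges[, 1], b = litEdges[, 2],
                                     stringsAsFactors = FALSE))
  expect_equal(ov2$counts[["both"]], ov$counts[["both"]])
  expect_equal(ov2$counts[["lit_only"]], ov$counts[["ppi_only"]])
  expect_equal(ov2$counts[["ppi_only"]], ov$counts[["lit_only"]])
})

fig4cFixture <- function() {
  # anchor TNF-TNFRSF1A shared by both sources; TNF has two literature-only
  # neighbors, TNFRSF1A four PPI-only neighbors
  lit <- makeNetwork(
    data.frame(id = c("TNF", "TNFRSF1A", "IL6", "IL1B"), ntype = "gene",
               stringsAsFactors = FALSE),
    data.frame(a = c("TNF", "IL6", "IL1B"),
               b = c("TNFRSF1A", "TNF", "TNF"),
               n_sentences = 1L, max_score = 1, source_tag = "literature",
               stringsAsFactors = FALSE))
  ppi <- data.frame(
    a = c("TNF", "TNFRSF1A", "TNFRSF1A", "TNFRSF1A", "TNFRSF1A"),
    b = c("TNFRSF1A", "MAPK1", "TRAF1", "CHUK", "HSP90AA1"),
    stringsAsFactors = FALSE)
  overlapPpi(lit, ppi, restrictToLitGenes = FALSE)$merged
}

test_that("indirect hypotheses form the cross product of exclusive neighbors", {
  merged <- fig4cFixture()
  hyp <- indirectHypotheses(merged, c("TNF", "TNFRSF1A"))
  expect_equal(nrow(hyp), 8L)   # 2 literature-only x 4 ppi-only
  expect_setequal(unique(hyp$x), c("IL6", "IL1B"))
  expect_setequal(unique(hyp$y), c("MAPK1", "TRAF1", "CHUK", "HSP90AA1"))
  expect_true(all(apply(hyp[, c("x", "anchor_a", "anchor_b", "y")], 1,
                        function(r) length(unique(r)) == 4L)))
})

test_that("anchors without exclusive neighbors yield no hypotheses", {
  lit <- litFixture()
  ov <- overlapPpi(lit, data.frame(a = c("A1", "A1"), b = c("B1", "C1"),
                                   stringsAsFactors = FALSE))
  hyp <- indirectHypotheses(ov$merged, c("A1", "B1"))
  expect_equal(nrow(hyp), 0L)
  expect_error(indirectHypotheses(ov$merged, c("B1", "C1")), "anchor")
})
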