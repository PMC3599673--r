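test_that("degree centrality counts incident edges", {
  star <- starNetwork(3)
  d <- degreeCentrality(star)
  expect_equal(d[["hub"]], 3)
  expect_equal(unname(d[paste0("leaf", 1:3)]), rep(1, 3))
  iso <- makeNetwork(data.frame(id = c("a", "b", "c"), ntype = "gene"),
                     data.frame(a = "a", b = "b", n_sentences = 1L,
                                max_score = 1, source_tag = "literature"))
  expect_equal(degreeCentrality(iso)[["c"]], 0)
  expect_equal(unname(degreeCentrality(triangleNetwork())), rep(2, 3))
})

test_that("eigenvector centrality matches symmetry and the dense oracle", {
  tri <- eigenvectorCentrality(triangleNetwork())
  expect_equal(unname(tri), rep(1 / sqrt(3), 3), tolerance = 1e-8)
  p3 <- eigenvectorCentrality(p3Network())
  expect_gt(p3[["b"]], p3[["a"]])
  expect_gt(p3[["b"]], p3[["c"]])
  expect_error(eigenvectorCentrality(buildNetwork(NULL)), "edge")

  set.seed(88)
  for (trial in seq_len(100)) {
    net <- randomConnectedNetwork(sample(3:8, 1))
    got <- eigenvectorCentrality(net)
    want <- denseEigenOracle(net)
    expect_equal(unname(got[names(want)]), unname(want), tolerance = 1e-8)
  }
})

test_that("closeness centrality applies the component-size correction", {
  p3 <- closenessCentrality(p3Network())
  expect_equal(p3[["b"]], 1.0)
  expect_equal(p3[["a"]], (2 / 3) * (2 / 2))
  k2iso <- makeNetwork(data.frame(id = c("a", "b", "c"), ntype = "gene"),
                       data.frame(a = "a", b = "b", n_sentences = 1L,
                                  max_score = 1, source_tag = "literature"))
  cc <- closenessCentrality(k2iso)
  expect_equal(cc[["a"]], 0.5)
  expect_equal(cc[["b"]], 0.5)
  expect_equal(cc[["c"]], 0)
})

test_that("betweenness centrality matches hand counts and brute force", {
  p3 <- betweennessCentrality(p3Network())
  expect_equal(p3[["b"]], 1.0)
  expect_equal(p3[["a"]], 0)
  star <- betweennessCentrality(starNetwork(4))
  expect_equal(star[["hub"]], choose(4, 2))

  set.seed(99)
  for (trial in seq_len(100)) {
    net <- randomTestNetwork(sample(2:8, 1), p = 0.5)
    got <- betweennessCentrality(net)
    want <- bruteBetweenness(net)
    expect_equal(unname(got[names(want)]), unname(want), tolerance = 1e-9)
  }
})

test_that("all four metrics are invariant under node relabeling", {
  set.seed(123)
  net <- randomConnectedNetwork(7)
  ids <- networkNodes(net)$id
  perm <- stats::setNames(paste0("z", sample(seq_along(ids))), ids)
  e <- networkEdges(net)
  relabeled <- makeNetwork(
    data.frame(id = unname(perm[ids]), ntype = "gene",
               stringsAsFactors = FALSE),
    data.frame(a = unname(perm[e$a]), b = unname(perm[e$b]),
               n_sentences = e$n_sentences, max_score = e$max_score,
               source_tag = e$source_tag, stringsAsFactors = FALSE))
  for (fn in list(degreeCentrality, eigenvectorCentrality,
                  closenessCentrality, betweennessCentrality)) {
    orig <- fn(net)
    new_ <- fn(relabeled)
    expect_equal(unname(new_[unname(perm[ids])]), unname(orig[ids]),
                 tolerance = 1e-7)
  }
})

test_that("adding an edge never decreases an endpoint's degree", {
  set.seed(31)
  net <- randomTestNetwork(6, p = 0.3)
  d0 <- degreeCentrality(net)
  e <- networkEdges(net)
  ids <- networkNodes(net)$id
  pairs <- utils::combn(ids, 2)
  keys <- paste(pmin(pairs[1, ], pairs[2, ]), pmax(pairs[1, ], pairs[2, ]))
  have <- paste(e$a, e$b)
  free <- which(!(keys %in% have))
  if (length(free)) {
    pick <- pairs[, free[1]]
    e2 <- rbind(e, data.frame(a = min(pick), b = max(pick),
                              n_sentences = 1L, max_score = 1,
                              source_tag = "literature"))
    d1 <- degreeCentrality(makeNetwork(networkNodes(net), e2))
    expect_true(all(d1[names(d0)] >= d0))
  }
})

test_that("ranking is a deterministic permutation with id tie-breaks", {
  net <- starNetwork(3)
  rep_ <- centralityReport(net)
  expect_setequal(sort(rep_$rank_degree), seq_len(nrow(rep_)))
  # leaves tie on every metric; ids ascending break the tie
  leaves <- rep_[rep_$node != "hub", ]
  expect_equal(leaves$node[order(leaves$rank_degree)],
               sort(leaves$node))
  expect_equal(topK(rep_, "degree", 1), "hub")
  expect_length(topK(rep_, "degree", 10), 4L)  # shorter than k
})

test_that("top-set comparison reproduces hand-computed groups", {
  netA <- makeNetwork(
    data.frame(id = c("g1", "g2", "g3", "g4", "g5", "g6"), ntype = "gene"),
    data.frame(a = c("g1", "g1", "g1", "g2", "g5"),
               b = c("g2", "g3", "g4", "g3", "g6"),
               n_sentences = 1L, max_score = 1, source_tag = "literature"))
  netB <- makeNetwork(
    data.frame(id = c("g1", "g2", "g7", "g8"), ntype = "gene"),
    data.frame(a = c("g1", "g7", "g1"), b = c("g2", "g8", "g7"),
               n_sentences = 1L, max_score = 1, source_tag = "literature"))
  ra <- centralityReport(netA); rb <- centralityReport(netB)
  cmp <- compareTopSets(ra, rb, k = 2)
  # hand-ranked: A top-2 by any metric = {g1 (top everywhere), g2, g3, g5}
  #   degree: g1(3) > g2=g3(2); eigen: g1 > g2/g3; betweenness: g1, g5/g2...
  expect_true("g1" %in% cmp$both)
  expect_true(all(cmp$a_only %in% c("g2", "g3", "g4", "g5", "g6")))
  expect_true(all(cmp$b_only %in% c("g7", "g8")))
  expect_length(intersect(cmp$both, cmp$a_only), 0L)
  expect_length(intersect(cmp$both, cmp$b_only), 0L)

  same <- compareTopSets(ra, ra, k = 2)
  expect_length(same$a_only, 0L)
  expect_length(same$b_only, 0L)

  disjointB <- makeNetwork(
    data.frame(id = c("h1", "h2"), ntype = "gene"),
    data.frame(a = "h1", b = "h2", n_sentences = 1L, max_score = 1,
               source_tag = "literature"))
  cmp2 <- compareTopSets(ra, centralityReport(disjointB), k = 2)
  expect_length(cmp2$both, 0L)
})

test_that("the comparison table prints ranks with --- beyond k", {
  netA <- starNetwork(4)
  netB <- p3Network()
  tab <- comparisonTable(centralityReport(netA), centralityReport(netB),
                         k = 1)
  expect_true(all(c("gene", "a_D", "b_D", "a_B", "b_C") %in% colnames(tab)))
  hub <- tab[tab$gene == "hub", ]
  expect_equal(hub$a_D, "1")
  expect_equal(hub$b_D, "---")
})

test_that("vaccine nodes are excluded from ranking by default", {
  net <- makeNetwork(
    data.frame(id = c("g1", "g2", "vaccine"),
               ntype = c("gene", "gene", "vaccine")),
    data.frame(a = c("g1", "g1"), b = c("g2", "vaccine"),
               n_sentences = 1L, max_score = 1, source_tag = "literature"))
  rep_ <- centralityReport(net)
  expect_true(is.na(rep_$rank_degree[rep_$node == "vaccine"]))
  expect_false("vaccine" %in% topKAny(rep_, 10))
  repAll <- centralityReport(net, rankNodes = "all")
  expect_false(any(is.na(repAll$rank_degree)))
})
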