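test_that("CoNLL-U reading validates structure and preserves order", {
  f <- writeTempLines(c(toyParseLines("d1", 0L),
                        toyParseLines("d1", 1L, verb = "inhibits",
                                      lemma = "inhibit")), ".conllu")
  parses <- readConllu(f)
  expect_length(parses, 2L)
  expect_equal(parses[[1]]$doc_id, "d1")
  expect_equal(parses[[2]]$sent_index, 1L)
  expect_equal(nrow(parses[[1]]$tokens), 4L)
  expect_equal(sum(parses[[1]]$tokens$head == 0L), 1L)

  dangling <- writeTempLines(c("# doc_id = d1", "# sent_index = 0",
    paste(1, "a", "a", "_", "_", "_", 9, "nsubj", "_", "_", sep = "\t"),
    paste(2, "b", "b", "_", "_", "_", 0, "root", "_", "_", sep = "\t"), ""),
    ".conllu")
  expect_error(readConllu(dangling), "absent token")

  noroot <- writeTempLines(c("# doc_id = d1", "# sent_index = 0",
    paste(1, "a", "a", "_", "_", "_", 2, "nsubj", "_", "_", sep = "\t"),
    paste(2, "b", "b", "_", "_", "_", 1, "dep", "_", "_", sep = "\t"), ""),
    ".conllu")
  expect_error(readConllu(noroot), "root")
})

test_that("candidate pairs require a keyword and distinct normalized entities", {
  lex <- toyLexicon()
  kw <- c("activate", "bind")
  s <- sentenceRow("IL6 activates STAT3.")
  m <- tagSentence(s, lex)
  cand <- findCandidates(s, m, kw)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$pair_kind, "gene_gene")
  expect_equal(cand$keyword, "activates")

  s2 <- sentenceRow("IL6 and STAT3 were measured.")
  expect_equal(nrow(findCandidates(s2, tagSentence(s2, lex), kw)), 0L)

  s3 <- sentenceRow("IL6 binds IL-6.")  # same normalized gene twice
  expect_equal(nrow(findCandidates(s3, tagSentence(s3, lex), kw)), 0L)

  expect_error(findCandidates(s, m, character()), "empty")
})

test_that("keyword matching stems inflected forms to base entries", {
  lex <- toyLexicon()
  for (txt in c("IL6 binding of STAT3.", "IL6 was induced by STAT3.",
                "IL6 suppresses STAT3.")) {
    s <- sentenceRow(txt)
    cand <- findCandidates(s, tagSentence(s, lex),
                           c("bind", "induce", "suppress"))
    expect_equal(nrow(cand), 1L)
  }
})

test_that("gene-vaccine candidates have exactly one gene member", {
  lex <- toyLexicon()
  onto <- toyOntology()
  s <- sentenceRow("BCG vaccine activates IL6 and flu vaccine.")
  m <- tagSentence(s, lex, onto)
  cand <- findCandidates(s, m, "activate")
  gv <- cand[cand$pair_kind == "gene_vaccine", ]
  expect_equal(nrow(gv), 2L)   # IL6 with each vaccine; no vaccine-vaccine
  expect_equal(nrow(cand), 2L)
})

test_that("shortest dependency path matches the hand-built parse", {
  f <- writeTempLines(toyParseLines(), ".conllu")
  p <- readConllu(f)[[1]]
  a <- data.frame(char_start = 0L, char_end = 4L)
  b <- data.frame(char_start = 15L, char_end = 19L)
  dp <- shortestDepPath(p, a, b)
  expect_equal(dp$sequence,
               c("ENTITYA", "nsubj<", "activate", "dobj>", "ENTITYB"))
  expect_equal(length(dp$nodeTokens), length(dp$edgeTokens) + 1L)
  expect_equal(dp$sequence[1], "ENTITYA")
  expect_equal(dp$sequence[length(dp$sequence)], "ENTITYB")

  # degenerate: both mentions on the same token
  expect_error(shortestDepPath(p, a, a), "degenerate")
})

test_that("reversing the pair flips the direction markers", {
  f <- writeTempLines(toyParseLines(), ".conllu")
  p <- readConllu(f)[[1]]
  a <- data.frame(char_start = 0L, char_end = 4L)
  b <- data.frame(char_start = 15L, char_end = 19L)
  fwd <- shortestDepPath(p, a, b)$sequence
  rev_ <- shortestDepPath(p, b, a)$sequence
  flip <- function(x) {
    out <- rev(x)
    swap <- chartr("<>", "><", out)
    out[grepl("[<>]$", out)] <- swap[grepl("[<>]$", out)]
    out
  }
  mapped <- flip(fwd)
  mapped[mapped == "ENTITYA"] <- "TMP"
  mapped[mapped == "ENTITYB"] <- "ENTITYA"
  mapped[mapped == "TMP"] <- "ENTITYB"
  expect_equal(rev_, mapped)
})

test_that("path length equals BFS tree distance on random trees", {
  set.seed(77)
  for (trial in seq_len(200)) {
    n <- sample(2:10, 1)
    p <- randomParse(n)
    ab <- sample(n, 2)
    # mention spans aligned to single tokens of the reconstructed text
    pos <- cumsum(nchar(p$tokens$form) + 1L)
    starts <- c(0L, pos[-n])
    a <- data.frame(char_start = starts[ab[1]],
                    char_end = starts[ab[1]] + nchar(p$tokens$form[ab[1]]))
    b <- data.frame(char_start = starts[ab[2]],
                    char_end = starts[ab[2]] + nchar(p$tokens$form[ab[2]]))
    dp <- shortestDepPath(p, a, b)
    # oracle: BFS over the undirected tree edges
    adj <- lapply(seq_len(n), function(i) integer())
    for (i in seq_len(n)) {
      h <- p$tokens$head[i]
      if (h > 0L) { adj[[i]] <- c(adj[[i]], h); adj[[h]] <- c(adj[[h]], i) }
    }
    d <- rep(NA_integer_, n); d[ab[1]] <- 0L; q <- ab[1]
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (is.na(d[w])) { d[w] <- d[v] + 1L; q <- c(q, w) }
    }
    expect_equal(length(dp$edgeTokens), d[ab[2]])
  }
})

test_that("other tagged entities on the path become ENTITYX", {
  lines <- c("# doc_id = d1", "# sent_index = 0",
             "# text = ENTA binds ENTX with ENTB.",
    paste(1, "ENTA", "enta", "_", "_", "_", 2, "nsubj", "_", "_", sep = "\t"),
    paste(2, "binds", "bind", "_", "_", "_", 0, "root", "_", "_", sep = "\t"),
    paste(3, "ENTX", "entx", "_", "_", "_", 2, "dobj", "_", "_", sep = "\t"),
    paste(4, "with", "with", "_", "_", "_", 3, "prep", "_", "_", sep = "\t"),
    paste(5, "ENTB", "entb", "_", "_", "_", 4, "pobj", "_", "_", sep = "\t"),
    paste(6, ".", ".", "_", "_", "_", 2, "punct", "_", "_", sep = "\t"), "")
  p <- readConllu(writeTempLines(lines, ".conllu"))[[1]]
  mentions <- data.frame(doc_id = "d1", sent_index = 0L,
                         char_start = c(0L, 11L, 21L),
                         char_end = c(4L, 15L, 25L),
                         surface = c("ENTA", "ENTX", "ENTB"),
                         etype = "gene",
                         norm_id = c("A", "X", "B"),
                         stringsAsFactors = FALSE)
  a <- mentions[1, ]; b <- mentions[3, ]
  dp <- shortestDepPath(p, a, b, mentions)
  expect_true("ENTITYX" %in% dp$sequence)
  expect_false("entx" %in% dp$sequence)
})

test_that("extractPaths drops degenerate or unparsed candidates with a count", {
  f <- writeTempLines(toyParseLines(), ".conllu")
  parses <- indexParses(readConllu(f))
  cand <- rbind(
    data.frame(doc_id = "d1", sent_index = 0L, a_norm = "ENTA",
               a_etype = "gene", a_start = 0L, a_end = 4L, b_norm = "ENTB",
               b_etype = "gene", b_start = 15L, b_end = 19L,
               keyword = "activates", pair_kind = "gene_gene",
               stringsAsFactors = FALSE),
    data.frame(doc_id = "d9", sent_index = 0L, a_norm = "X",
               a_etype = "gene", a_start = 0L, a_end = 1L, b_norm = "Y",
               b_etype = "gene", b_start = 2L, b_end = 3L,
               keyword = "binds", pair_kind = "gene_gene",
               stringsAsFactors = FALSE))
  out <- extractPaths(cand, parses)
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "n_dropped"), 1L)
  expect_equal(out$path, "ENTITYA nsubj< activate dobj> ENTITYB")
})
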