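# Synthetic fixture bundle: templated corpus with hand-authored dependency
# parses, planted true interactions, toy ontology, and a separable labeled
# path training set.

#' Configuration for the synthetic fixture generator
#'
#' @param nGenes number of genes in the lexicon (>= 4).
#' @param nVaccines number of leaf vaccine terms (>= 1).
#' @param nDocs number of documents.
#' @param sentencesPerDoc sentences per document (first sentence is the
#'   title).
#' @param pPositive fraction of sentences drawn from interaction templates.
#' @param nLabeledPaths size of the labeled path training set.
#' @param seed integer seed.
#' @return validated config list.
#' @export
fixtureConfig <- function(nGenes = 30L, nVaccines = 5L, nDocs = 200L,
                          sentencesPerDoc = 3L, pPositive = 0.4,
                          nLabeledPaths = 120L, seed = 42L) {
  stopifnot(nGenes >= 4L, nVaccines >= 1L, nDocs >= 1L,
            sentencesPerDoc >= 1L, pPositive >= 0, pPositive <= 1,
            nLabeledPaths >= 20L)
  list(nGenes = as.integer(nGenes), nVaccines = as.integer(nVaccines),
       nDocs = as.integer(nDocs),
       sentencesPerDoc = as.integer(sentencesPerDoc),
       pPositive = pPositive, nLabeledPaths = as.integer(nLabeledPaths),
       seed = as.integer(seed))
}

.synVerbs <- data.frame(
  third = c("activates", "inhibits", "binds", "suppresses", "stimulates",
            "induces"),
  past = c("activated", "inhibited", "bound", "suppressed", "stimulated",
           "induced"),
  lemma = c("activate", "inhibit", "bind", "suppress", "stimulate",
            "induce"),
  stringsAsFactors = FALSE)

.synGeneSymbols <- function(nGenes) {
  syms <- paste0("FG", seq_len(nGenes))
  syms[1] <- "AB"  # 2-letter official symbol exercising the case rule
  syms
}

.synLexiconTable <- function(nGenes) {
  syms <- .synGeneSymbols(nGenes)
  name <- ifelse(syms == "AB", "antigen binder",
                 paste("fever gene", sub("^FG", "", syms)))
  synonyms <- ifelse(syms == "AB", "AB-p",
                     paste0("FG-", sub("^FG", "", syms)))
  # one deliberately ambiguous synonym shared by two genes
  if (nGenes >= 3L) {
    synonyms[2] <- paste0(synonyms[2], "|p40")
    synonyms[3] <- paste0(synonyms[3], "|p40")
  }
  data.frame(symbol = syms, name = name, synonyms = synonyms,
             stringsAsFactors = FALSE)
}

.synVaccineLabels <- function(nVaccines) {
  base <- c("BCG", "RB51", "SC602", "WRSS1", "FluMax")
  if (nVaccines > length(base))
    base <- c(base, paste0("VaxSyn", seq_len(nVaccines - length(base))))
  paste(base[seq_len(nVaccines)], "vaccine")
}

.synOboLines <- function(nVaccines) {
  labels <- .synVaccineLabels(nVaccines)
  ids <- sprintf("VO:%07d", 100 + seq_len(nVaccines))
  lines <- c("format-version: 1.2",
             "ontology: toy-vaccine-ontology", "",
             "[Term]", "id: VO:0000001", "name: vaccine", "",
             "[Term]", "id: VO:0000002", "name: live attenuated vaccine",
             "is_a: VO:0000001 ! vaccine", "")
  for (i in seq_len(nVaccines)) {
    lines <- c(lines, "[Term]", paste0("id: ", ids[i]),
               paste0("name: ", labels[i]),
               "is_a: VO:0000002 ! live attenuated vaccine", "")
  }
  list(lines = lines, ids = ids, labels = labels)
}

.synKeywords <- function() {
  c("bind", "bound", "activate", "induce", "inhibit", "suppress", "regulate",
    "interact", "stimulate", "phosphorylate", "associate", "block",
    "mediate", "modulate", "promote", "enhance", "attenuate",
    "upregulate", "downregulate", "trigger", "repress", "degrade",
    "cleave", "recruit", "target", "ligate", "antagonize")
}

# --- template machinery -----------------------------------------------------
# A template is a list of slots; each slot is either
#   list(word=, lemma=, head=<slot index, 0 = root>, deprel=)
# or
#   list(entity=<"A"|"B">, head=, deprel=)  -- expanded to the entity's
# tokens: the last token is the phrase head carrying the slot's relation,
# preceding tokens attach to it ("The" as det, others as compound).
.instantiateTemplate <- function(template, surfA = NULL, surfB = NULL) {
  forms <- character(); lemmas <- character()
  heads <- integer(); deprels <- character()
  slotHeadTid <- integer(length(template))
  pending <- list()
  for (si in seq_along(template)) {
    slot <- template[[si]]
    if (!is.null(slot$entity)) {
      surf <- if (slot$entity == "A") surfA else surfB
      toks <- strsplit(surf, " ", fixed = TRUE)[[1]]
      base <- length(forms)
      np <- length(toks)
      for (k in seq_len(np)) {
        forms <- c(forms, toks[k])
        lemmas <- c(lemmas, tolower(toks[k]))
        if (k < np) {
          heads <- c(heads, base + np)  # attach to phrase head
          deprels <- c(deprels,
                       if (tolower(toks[k]) == "the") "det" else "compound")
        } else {
          heads <- c(heads, NA_integer_)  # resolved from slot later
          deprels <- c(deprels, slot$deprel)
          pending[[length(pending) + 1L]] <- list(tid = base + np,
                                                  headSlot = slot$head)
        }
      }
      slotHeadTid[si] <- base + np
    } else {
      forms <- c(forms, slot$word)
      lemmas <- c(lemmas, slot$lemma)
      heads <- c(heads, NA_integer_)
      deprels <- c(deprels, slot$deprel)
      pending[[length(pending) + 1L]] <- list(tid = length(forms),
                                              headSlot = slot$head)
      slotHeadTid[si] <- length(forms)
    }
  }
  for (p in pending) {
    heads[p$tid] <- if (p$headSlot == 0L) 0L else slotHeadTid[p$headSlot]
  }
  text <- paste(forms, collapse = " ")
  text <- gsub(" ([.,])", "\\1", text)
  list(text = text,
       tokens = data.frame(tid = seq_along(forms), form = forms,
                           lemma = lemmas, head = heads, deprel = deprels,
                           stringsAsFactors = FALSE))
}

.slot <- function(word, lemma, head, deprel)
  list(word = word, lemma = lemma, head = head, deprel = deprel)
.ent <- function(entity, head, deprel)
  list(entity = entity, head = head, deprel = deprel)

# Positive templates; `v` indexes .synVerbs.
.positiveTemplates <- function(v) {
  vb <- .synVerbs[v, ]
  list(
    active = list(.ent("A", 2L, "nsubj"),
                  .slot(vb$third, vb$lemma, 0L, "root"),
                  .ent("B", 2L, "dobj"),
                  .slot(".", ".", 2L, "punct")),
    passive = list(.ent("A", 3L, "nsubjpass"),
                   .slot("was", "be", 3L, "auxpass"),
                   .slot(vb$past, vb$lemma, 0L, "root"),
                   .slot("by", "by", 3L, "prep"),
                   .ent("B", 4L, "pobj"),
                   .slot(".", ".", 3L, "punct")),
    interact = list(.ent("A", 2L, "nsubj"),
                    .slot("interacts", "interact", 0L, "root"),
                    .slot("with", "with", 2L, "prep"),
                    .ent("B", 3L, "pobj"),
                    .slot(".", ".", 2L, "punct")),
    in_mice = list(.ent("A", 2L, "nsubj"),
                   .slot(vb$third, vb$lemma, 0L, "root"),
                   .ent("B", 2L, "dobj"),
                   .slot("in", "in", 2L, "prep"),
                   .slot("mice", "mouse", 4L, "pobj"),
                   .slot(".", ".", 2L, "punct")),
    adverb = list(.ent("A", 3L, "nsubj"),
                  .slot("directly", "directly", 3L, "advmod"),
                  .slot(vb$third, vb$lemma, 0L, "root"),
                  .ent("B", 3L, "dobj"),
                  .slot(".", ".", 3L, "punct")),
    strongly = list(.ent("A", 2L, "nsubj"),
                    .slot(vb$third, vb$lemma, 0L, "root"),
                    .ent("B", 2L, "dobj"),
                    .slot("strongly", "strongly", 2L, "advmod"),
                    .slot(".", ".", 2L, "punct")))
}

.negativeTemplates <- function(v) {
  vb <- .synVerbs[v, ]
  list(
    cooccur = list(.ent("A", 5L, "nsubjpass"),
                   .slot("and", "and", 1L, "cc"),
                   .ent("B", 1L, "conj"),
                   .slot("were", "be", 5L, "auxpass"),
                   .slot("measured", "measure", 0L, "root"),
                   .slot(".", ".", 5L, "punct")),
    offpath = list(.ent("A", 2L, "nsubj"),
                   .slot(vb$third, vb$lemma, 0L, "root"),
                   .slot("metabolism", "metabolism", 2L, "dobj"),
                   .slot("in", "in", 2L, "prep"),
                   .ent("B", 6L, "compound"),
                   .slot("cells", "cell", 4L, "pobj"),
                   .slot(".", ".", 2L, "punct")),
    single = list(.ent("A", 2L, "nsubj"),
                  .slot(vb$third, vb$lemma, 0L, "root"),
                  .slot("the", "the", 5L, "det"),
                  .slot("immune", "immune", 5L, "amod"),
                  .slot("response", "response", 2L, "dobj"),
                  .slot(".", ".", 2L, "punct")),
    empty = list(.slot("The", "the", 2L, "det"),
                 .slot("fever", "fever", 4L, "nsubj"),
                 .slot("was", "be", 4L, "cop"),
                 .slot("severe", "severe", 0L, "root"),
                 .slot(".", ".", 4L, "punct")))
}

# Canonical path shapes used for the labeled training set (placeholders
# only, so they match paths extracted from any instantiated sentence).
.labeledPathShapes <- function() {
  verbs <- .synVerbs$lemma
  pos <- c(
    vapply(verbs, function(v)
      paste("ENTITYA nsubj<", v, "dobj> ENTITYB"), character(1)),
    vapply(verbs, function(v)
      paste("ENTITYA nsubjpass<", v, "prep> by pobj> ENTITYB"),
      character(1)),
    "ENTITYA nsubj< interact prep> with pobj> ENTITYB")
  neg <- c(
    "ENTITYA conj> ENTITYB",
    vapply(verbs, function(v)
      paste("ENTITYA nsubj<", v, "prep> in pobj> cell compound> ENTITYB"),
      character(1)),
    "ENTITYA appos> ENTITYB")
  list(pos = unname(pos), neg = unname(neg))
}

#' Generate a labeled dependency-path training set
#'
#' Balanced set built from the generator's canonical positive and negative
#' path shapes, cycled to `n` rows.
#'
#' @param n number of rows.
#' @param seed seed controlling the row order.
#' @return data.frame with columns `path`, `label`.
#' @export
makeLabeledPaths <- function(n = 120L, seed = 42L) {
  shapes <- .labeledPathShapes()
  nPos <- ceiling(n / 2); nNeg <- n - nPos
  d <- data.frame(
    path = c(rep_len(shapes$pos, nPos), rep_len(shapes$neg, nNeg)),
    label = c(rep(1L, nPos), rep(-1L, nNeg)), stringsAsFactors = FALSE)
  set.seed(seed)
  d <- d[sample.int(nrow(d)), , drop = FALSE]
  rownames(d) <- NULL
  d
}

.conlluBlock <- function(docId, sentIndex, text, tokens) {
  c(paste0("# doc_id = ", docId),
    paste0("# sent_index = ", sentIndex),
    paste0("# text = ", text),
    vapply(seq_len(nrow(tokens)), function(i)
      paste(tokens$tid[i], tokens$form[i], tokens$lemma[i], "_", "_", "_",
            tokens$head[i], tokens$deprel[i], "_", "_", sep = "\t"),
      character(1)),
    "")
}

# generation-time structural check of a template parse
.checkParseTree <- function(tokens, where) {
  if (sum(tokens$head == 0L) != 1L)
    stop("template parse without unique root: ", where)
  if (any(tokens$head != 0L & !(tokens$head %in% tokens$tid)))
    stop("template parse with dangling head: ", where)
  # acyclic: every token reaches the root
  for (t in tokens$tid) {
    seen <- integer(); x <- t
    while (x != 0L) {
      if (x %in% seen) stop("template parse with head cycle: ", where)
      seen <- c(seen, x)
      x <- tokens$head[tokens$tid == x]
    }
  }
  invisible(TRUE)
}

#' Generate a complete synthetic fixture bundle
#'
#' Writes a self-consistent corpus (TSV), dependency parses (CoNLL-U, one
#' block per corpus sentence), gene lexicon, vaccine ontology (OBO),
#' interaction keywords, labeled training paths, planted truth edges, a PPI
#' edge list overlapping the truth, and a GMT annotation file. Positive
#' sentences instantiate interaction templates with hand-authored parse
#' skeletons; negative sentences are co-occurrence-without-keyword,
#' keyword-without-pair, or keyword-with-non-interacting-pair templates.
#' Deterministic given `config$seed`.
#'
#' @param config from [fixtureConfig()].
#' @param dir output directory (created if needed).
#' @return list of file paths (`corpus`, `conllu`, `lexicon`, `obo`,
#'   `keywords`, `labeled_paths`, `truth`, `ppi`, `gmt`, `config`) plus the
#'   in-memory planted-edge data.frame `truth_table`.
#' @export
generateFixtures <- function(config = fixtureConfig(), dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  lexTab <- .synLexiconTable(config$nGenes)
  syms <- lexTab$symbol
  obo <- .synOboLines(config$nVaccines)
  keywords <- .synKeywords()

  docIds <- sprintf("d%04d", seq_len(config$nDocs))
  corpus <- data.frame(doc_id = docIds, title = "", abstract = "",
                       stringsAsFactors = FALSE)
  conllu <- character()
  truth <- list()

  sampleGene <- function(exclude = character()) {
    pool <- setdiff(syms, exclude)
    s <- pool[sample.int(length(pool), 1L)]
    # occasionally surface the hyphenated synonym; normalization maps it back
    surf <- if (s != "AB" && stats::runif(1) < 0.1)
      paste0("FG-", sub("^FG", "", s)) else s
    list(norm = s, surface = surf)
  }

  for (d in seq_len(config$nDocs)) {
    sents <- character(config$sentencesPerDoc)
    for (s in seq_len(config$sentencesPerDoc)) {
      sIdx <- s - 1L
      positive <- stats::runif(1) < config$pPositive
      v <- sample.int(nrow(.synVerbs), 1L)
      if (positive) {
        tpl <- .positiveTemplates(v)[[sample.int(6L, 1L)]]
        gv <- stats::runif(1) < 0.25
        if (gv) {
          g <- sampleGene()
          specific <- stats::runif(1) < 0.6
          if (specific) {
            vi <- sample.int(config$nVaccines, 1L)
            vSurf <- obo$labels[vi]; vNorm <- obo$ids[vi]
          } else {
            vSurf <- "The vaccine"; vNorm <- "vaccine"
          }
          vaccineFirst <- stats::runif(1) < 0.5
          if (vaccineFirst) {
            inst <- .instantiateTemplate(tpl, vSurf, g$surface)
          } else {
            # vaccine in object position reads better without "The"
            if (!specific) vSurf <- "the vaccine"
            inst <- .instantiateTemplate(tpl, g$surface, vSurf)
          }
          truth[[length(truth) + 1L]] <- data.frame(
            kind = "gene_vaccine",
            a = min(g$norm, vNorm), b = max(g$norm, vNorm),
            stringsAsFactors = FALSE)
        } else {
          ga <- sampleGene(); gb <- sampleGene(exclude = ga$norm)
          inst <- .instantiateTemplate(tpl, ga$surface, gb$surface)
          truth[[length(truth) + 1L]] <- data.frame(
            kind = "gene_gene",
            a = min(ga$norm, gb$norm), b = max(ga$norm, gb$norm),
            stringsAsFactors = FALSE)
        }
      } else {
        which_ <- sample.int(4L, 1L, prob = c(0.3, 0.3, 0.2, 0.2))
        tpl <- .negativeTemplates(v)[[which_]]
        ga <- sampleGene(); gb <- sampleGene(exclude = ga$norm)
        inst <- .instantiateTemplate(tpl, ga$surface, gb$surface)
      }
      .checkParseTree(inst$tokens, paste(docIds[d], sIdx))
      sents[s] <- inst$text
      conllu <- c(conllu,
                  .conlluBlock(docIds[d], sIdx, inst$text, inst$tokens))
    }
    corpus$title[d] <- sents[1]
    if (config$sentencesPerDoc > 1L)
      corpus$abstract[d] <- paste(sents[-1], collapse = " ")
    else corpus$abstract[d] <- ""
  }

  truth <- if (length(truth)) unique(do.call(rbind, truth)) else
    data.frame(kind = character(), a = character(), b = character(),
               stringsAsFactors = FALSE)
  truth <- truth[order(truth$kind, truth$a, truth$b), , drop = FALSE]
  rownames(truth) <- NULL

  # PPI list: half of the planted gene-gene pairs plus extra pairs absent
  # from the truth (deterministic continuation of the seeded stream)
  gg <- truth[truth$kind == "gene_gene", , drop = FALSE]
  shared <- gg[seq_len(floor(nrow(gg) / 2)), c("a", "b"), drop = FALSE]
  extra <- list()
  ggKeys <- pairKey(gg$a, gg$b)
  tries <- 0L
  while (length(extra) < max(5L, nrow(shared) %/% 2L) && tries < 500L) {
    tries <- tries + 1L
    pick <- sample(syms, 2L)
    key <- pairKey(pick[1], pick[2])
    if (key %in% ggKeys) next
    extra[[key]] <- c(min(pick), max(pick))
  }
  ppi <- rbind(shared,
               if (length(extra)) {
                 m <- do.call(rbind, extra)
                 data.frame(a = m[, 1], b = m[, 2], stringsAsFactors = FALSE)
               })
  ppi <- unique(ppi[order(ppi$a, ppi$b), , drop = FALSE])

  # GMT: overlapping gene-set tiles over the lexicon + one fever set
  tile <- function(from, to) syms[seq(from, min(to, length(syms)))]
  third <- max(2L, config$nGenes %/% 3L)
  gmtRows <- c(
    paste(c("SYN:0001", "inflammatory response", tile(1L, third + 2L)),
          collapse = "\t"),
    paste(c("SYN:0002", "cytokine signaling",
            tile(third, 2L * third + 2L)), collapse = "\t"),
    paste(c("SYN:0003", "leukocyte activation",
            tile(2L * third, config$nGenes)), collapse = "\t"),
    paste(c("SYN:0004", "fever response", syms[seq_len(min(8L, third + 2L))]),
          collapse = "\t"))

  paths <- list(
    corpus = file.path(dir, "corpus.tsv"),
    conllu = file.path(dir, "parses.conllu"),
    lexicon = file.path(dir, "gene_lexicon.tsv"),
    obo = file.path(dir, "vaccine_ontology.obo"),
    keywords = file.path(dir, "keywords.txt"),
    labeled_paths = file.path(dir, "labeled_paths.tsv"),
    truth = file.path(dir, "truth_edges.tsv"),
    ppi = file.path(dir, "ppi.tsv"),
    gmt = file.path(dir, "annotations.gmt"),
    config = file.path(dir, "condl.cfg"))

  writeCorpus(corpus, paths$corpus)
  writeLines(conllu, paths$conllu)
  utils::write.table(lexTab, paths$lexicon, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(obo$lines, paths$obo)
  writeLines(keywords, paths$keywords)
  utils::write.table(makeLabeledPaths(config$nLabeledPaths, config$seed),
                     paths$labeled_paths, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ppi, paths$ppi, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(gmtRows, paths$gmt)
  # file paths are written relative to the bundle directory so a bundle is
  # byte-identical wherever it is generated; runPipeline resolves them
  writeLines(c(
    paste0("corpus = ", basename(paths$corpus)),
    paste0("conllu = ", basename(paths$conllu)),
    paste0("lexicon = ", basename(paths$lexicon)),
    paste0("obo = ", basename(paths$obo)),
    paste0("keywords = ", basename(paths$keywords)),
    paste0("labeled_paths = ", basename(paths$labeled_paths)),
    paste0("gmt = ", basename(paths$gmt)),
    paste0("ppi = ", basename(paths$ppi)),
    "gamma = 0.25", "C = 1.0", "threshold = 0", "k = 10",
    "alpha = 0.05", "method = ease",
    paste0("seed = ", config$seed)), paths$config)

  c(paths, list(truth_table = truth))
}

#' Precision/recall/F1 of extracted edges against planted truth
#'
#' Set-based evaluation over unordered pairs. Conventions for empty
#' denominators: with no predictions and no truth all three measures are
#' 1.0; predictions against an empty truth give precision 0; an empty
#' prediction set against nonempty truth gives recall 0.
#'
#' @param predicted data.frame with columns `a`, `b` (or character vector
#'   of `"a||b"` keys).
#' @param truth same format.
#' @return named numeric vector `precision`, `recall`, `f1`.
#' @export
evaluateExtraction <- function(predicted, truth) {
  asKeys <- function(x) {
    if (is.character(x)) return(unique(x))
    if (!nrow(x)) return(character())
    unique(pairKey(x$a, x$b))
  }
  p <- asKeys(predicted); t <- asKeys(truth)
  if (!length(p) && !length(t))
    return(c(precision = 1, recall = 1, f1 = 1))
  tp <- length(intersect(p, t))
  precision <- if (!length(p)) { if (length(t)) 0 else 1 } else tp / length(p)
  if (length(p) && !length(t)) precision <- 0
  recall <- if (!length(t)) 1 else tp / length(t)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}
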