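# End-to-end pipeline: ingest -> tag -> candidates -> paths -> classify ->
# networks -> centrality -> enrichment -> PPI overlap, with stage-count
# logging.

#' Read a flat key = value pipeline configuration file
#'
#' Lines of the form `key = value`; `#` comments and blank lines ignored.
#'
#' @param path config file.
#' @return named list of character values.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)$",
                                  lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  stats::setNames(lapply(kv, function(x) trimws(x[3])),
                  vapply(kv, `[`, character(1), 2))
}

.cfgDefaults <- function() {
  list(gamma = 0.25, C = 1.0, threshold = 0, k = 10L, alpha = 0.05,
       method = "ease", seed = 42L)
}

# normalize a user config list: required paths + typed hyperparameters
.normalizeConfig <- function(config) {
  need <- c("corpus", "conllu", "lexicon", "obo", "keywords",
            "labeled_paths")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("config misses required key(s): ", paste(missing, collapse = ", "))
  for (key in need) {
    if (!file.exists(config[[key]]))
      stop("configured ", key, " file not found: ", config[[key]])
  }
  for (key in c("gmt", "ppi")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      stop("configured ", key, " file not found: ", config[[key]])
  }
  def <- .cfgDefaults()
  for (key in c("gamma", "C", "threshold", "k", "alpha", "seed")) {
    config[[key]] <- if (is.null(config[[key]])) def[[key]]
                     else as.numeric(config[[key]])
  }
  config$k <- as.integer(config$k)
  config$seed <- as.integer(config$seed)
  if (is.null(config$method)) config$method <- def$method
  config$method <- match.arg(config$method, c("ease", "fisher"))
  if (config$k < 1L) stop("k must be >= 1")
  if (config$alpha <= 0 || config$alpha >= 1)
    stop("alpha must lie in (0, 1)")
  config
}

#' Run the full literature-mining pipeline
#'
#' Executes every stage on the configured inputs and writes all outputs
#' plus a JSON log of per-stage counts into `outDir`. Deterministic given
#' the configured seed.
#'
#' Outputs: `mentions.tsv`, `candidates.tsv`, `scored.tsv`, `model.json`,
#' gene-gene networks for the full corpus and the vaccine / ontology-term
#' subsets (`net_*.graphml` + `.sif`), the gene-vaccine network, centrality
#' reports, the two-network top-k comparison table, `enrichment.tsv`,
#' `ppi_merged.graphml`, `overlap_counts.json`, and `log.json`.
#'
#' @param config named list or path to a `key = value` file (see
#'   [readPipelineConfig()]); required keys `corpus`, `conllu`, `lexicon`,
#'   `obo`, `keywords`, `labeled_paths`; optional `gmt`, `ppi`, `gamma`,
#'   `C`, `threshold`, `k`, `alpha`, `method`, `seed`.
#' @param outDir run directory (created).
#' @return invisibly, a list with the main in-memory results (`networks`,
#'   `reports`, `comparison`, `enrichment`, `overlap`, `log`).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L) {
    base <- dirname(config)
    config <- readPipelineConfig(config)
    # resolve file paths relative to the config file's directory
    for (key in c("corpus", "conllu", "lexicon", "obo", "keywords",
                  "labeled_paths", "gmt", "ppi")) {
      v <- config[[key]]
      if (!is.null(v) && !file.exists(v) &&
          file.exists(file.path(base, v)))
        config[[key]] <- file.path(base, v)
    }
  }
  config <- .normalizeConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- list(config = config[order(names(config))])

  docs <- readCorpus(config$corpus, format = "tsv")
  sentences <- splitCorpusSentences(docs)
  log$documents <- nrow(docs)
  log$sentences <- nrow(sentences)

  lex <- loadGeneLexicon(config$lexicon)
  onto <- loadObo(config$obo)
  rootId <- termByLabel(onto, "vaccine")
  mentions <- tagCorpus(sentences, lex, onto, rootId = rootId)
  writeMentions(mentions, file.path(outDir, "mentions.tsv"))
  log$mentions <- nrow(mentions)
  log$gene_mentions <- sum(mentions$etype == "gene")
  log$vaccine_mentions <- sum(mentions$etype != "gene")

  keywords <- defaultKeywords(config$keywords)
  candidates <- findCorpusCandidates(sentences, mentions, keywords)
  log$candidates <- nrow(candidates)

  parses <- indexParses(readConllu(config$conllu))
  log$parses <- length(parses)
  candPaths <- extractPaths(candidates, parses, mentions)
  log$paths <- nrow(candPaths)
  log$paths_dropped <- attr(candPaths, "n_dropped")
  utils::write.table(candPaths, file.path(outDir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  labeled <- readLabeledPaths(config$labeled_paths)
  model <- trainPathSVM(labeled$path, labeled$label, C = config$C,
                        gamma = config$gamma, seed = config$seed)
  writeKernelModel(model, file.path(outDir, "model.json"))
  scored <- scoreCandidates(model, candPaths, threshold = config$threshold)
  utils::write.table(scored, file.path(outDir, "scored.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log$positive_pairs <- sum(scored$is_positive)

  # full gene-gene network and subsets
  netGG <- buildNetwork(scored, pairKinds = "gene_gene")
  vaccineDocs <- subsetCorpus(docs, defaultVaccineVariants())$doc_id
  leafLabels <- unlist(lapply(leafTerms(onto, rootId), function(id)
    c(onto@labels[[id]], onto@synonyms[[id]])), use.names = FALSE)
  ontoDocs <- subsetCorpus(docs, unique(c(leafLabels,
                                          defaultVaccineVariants())))$doc_id
  netVaccine <- subnetworkByCorpus(scored, vaccineDocs,
                                   pairKinds = "gene_gene")
  netOnto <- subnetworkByCorpus(scored, ontoDocs, pairKinds = "gene_gene")
  netGV <- buildNetwork(scored)
  for (nm in c("net_gene_gene", "net_vaccine_subset", "net_onto_subset",
               "net_gene_vaccine")) {
    net <- switch(nm, net_gene_gene = netGG, net_vaccine_subset = netVaccine,
                  net_onto_subset = netOnto, net_gene_vaccine = netGV)
    exportNetwork(net, file.path(outDir, paste0(nm, ".graphml")), "graphml")
    exportNetwork(net, file.path(outDir, paste0(nm, ".sif")), "sif")
  }
  log$network_nodes <- nrow(netGG@nodes)
  log$network_edges <- nrow(netGG@edges)
  log$vaccine_subset_docs <- length(vaccineDocs)
  log$onto_subset_docs <- length(ontoDocs)
  log$gene_vaccine_edges <- nrow(netGV@edges) - nrow(netGG@edges)

  # centrality on the full and the ontology-expanded vaccine subset network
  reports <- list(); comparison <- NULL
  if (nrow(netGG@edges)) {
    reports$full <- centralityReport(netGG)
    utils::write.table(reports$full, file.path(outDir, "centrality_full.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (nrow(netOnto@edges)) {
    reports$vaccine <- centralityReport(netOnto)
    utils::write.table(reports$vaccine,
                       file.path(outDir, "centrality_vaccine.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(reports) == 2L) {
    comparison <- comparisonTable(reports$full, reports$vaccine,
                                  k = config$k)
    utils::write.table(comparison, file.path(outDir, "top_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  enrichment <- NULL
  if (!is.null(config$gmt) && nrow(netGG@nodes)) {
    db <- loadGmt(config$gmt)
    enrichment <- enrich(networkGenes(netGG), db, method = config$method,
                         alpha = config$alpha)
    utils::write.table(enrichment, file.path(outDir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log$enriched_terms <- sum(enrichment$significant)
  }

  overlap <- NULL
  if (!is.null(config$ppi)) {
    ppi <- readPpi(config$ppi, lex)
    overlap <- overlapPpi(netGV, ppi)
    exportNetwork(overlap$merged, file.path(outDir, "ppi_merged.graphml"),
                  "graphml")
    jsonlite::write_json(as.list(overlap$counts),
                         file.path(outDir, "overlap_counts.json"),
                         auto_unbox = TRUE, digits = NA)
    log$ppi_edges <- nrow(ppi)
    log$ppi_shared <- unname(overlap$counts[["both"]])
  }

  jsonlite::write_json(log, file.path(outDir, "log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(networks = list(gene_gene = netGG, vaccine = netVaccine,
                                 onto = netOnto, gene_vaccine = netGV),
                 reports = reports, comparison = comparison,
                 enrichment = enrichment, overlap = overlap,
                 scored = scored, log = log))
}
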