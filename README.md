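# condl

Literature-derived gene–gene and gene–vaccine interaction networks, with
centrality-based gene prioritization, gene-set over-representation and
protein–protein-interaction (PPI) overlap analysis.

## The problem

Fever is one of the most common adverse events of vaccination, and the
genes behind it — the endogenous pyrogens IL-1β, IL-6 and TNF, their
receptors, the arachidonic-acid pathway — are described across enormous
numbers of abstracts, not in any single curated resource. `condl` is for
researchers who want to turn an abstract corpus plus standard resource
files (a gene lexicon, a vaccine ontology in OBO, dependency parses in
CoNLL-U, an interaction keyword list) into analyzable interaction
networks, and then ask *which genes matter* in them.

## The method

The pipeline works at the sentence level:

1. **Tag** gene mentions with a dictionary- and rule-based tagger
   (longest match, case-sensitive matching for ≤ 2-character symbols,
   ambiguous surfaces dropped) normalized to official symbols, and vaccine
   mentions from the leaf terms of an `is_a` ontology plus a generic
   surface-variant list.
2. **Select candidates**: sentences with an interaction keyword and two
   distinct entities (gene–gene or gene–vaccine).
3. **Classify** the shortest dependency path between the entity head
   tokens with a support vector machine over an edit-distance kernel

   `k(x, y) = exp(-γ · d(x, y))`,

   where `d` is the token-level Levenshtein distance between
   placeholder-normalized path sequences such as
   `ENTITYA nsubj< activate dobj> ENTITYB`. The Gram matrix is spectrally
   repaired if indefinite; pairs with **positive** decision values become
   interactions.
4. **Analyze**: assemble evidence-carrying undirected networks (full
   corpus and vaccine-related subsets); rank genes by degree, eigenvector,
   closeness and betweenness centrality and compare the top-k sets of two
   networks; test gene sets for over-represented annotation terms
   (Fisher or the conservative EASE variant, Benjamini–Hochberg at 0.05);
   overlap the network with an external PPI edge list and propose
   indirect interactions across shared anchor edges.

A synthetic-fixture generator produces a complete, self-consistent input
bundle with planted true interactions, so the whole pipeline is testable
end to end without any external resource.

## Worked example

Generate a 40-document synthetic corpus and run the full pipeline:

```r
library(condl)

fx  <- generateFixtures(fixtureConfig(nDocs = 40, seed = 7), "fixtures")
res <- runPipeline(fx$config, "rundir")

res$networks$gene_gene
#> InteractionNetwork: 28 nodes ( 28 genes, 0 vaccines ), 34 edges

rep <- res$reports$full
head(rep[order(rep$rank_degree),
         c("node", "degree", "eigenvector", "betweenness")], 3)
#>    node degree eigenvector betweenness
#> 22 FG30      6   0.4331673   174.08333
#> 11  FG2      5   0.3435216    67.91667
#> 9  FG18      4   0.1944181   124.58333

evaluateExtraction(networkEdges(res$networks$gene_gene)[, c("a", "b")],
                   fx$truth_table[fx$truth_table$kind == "gene_gene",
                                  c("a", "b")])
#> precision    recall        f1
#>         1         1         1

res$overlap$counts
#> lit_only ppi_only     both
#>       17        8       17
```

The run directory contains every intermediate artifact: `mentions.tsv`,
`candidates.tsv` (with dependency paths), `scored.tsv`, the trained model
(`model.json`), Cytoscape-loadable networks (`*.graphml`, `*.sif`),
centrality reports, the two-network top-k comparison table,
`enrichment.tsv`, the merged literature+PPI network, and a `log.json`
recording the configuration and per-stage counts. The extraction
evaluation above reads: every planted gene–gene interaction was recovered
(recall 1) and nothing spurious was added (precision 1). Of the 34
literature edges, 17 are independently present in the bundled PPI list
(`both`), and 8 PPI edges among the network's genes were not found in the
text.

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "condl.R", package = "condl"))')" \
    simulate seed=42 out=fixtures/
```

with subcommands `simulate`, `run`, `ingest`, `subset`, `tag`, `train`,
`classify`, `network`, `centrality`, `compare`, `enrich`, `overlap`, and
`hypothesize`.

## Vignette

`vignettes/condl-methods.Rmd` documents the model and its assumptions: the
tagging rules, the path encoding, the kernel and its PSD repair, the
centrality definitions (including disconnected-graph handling), the
enrichment statistics, and what the synthetic bundle does and does not
emulate about real literature.
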