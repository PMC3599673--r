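---
title: "Mining gene and vaccine interaction networks from literature: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining gene and vaccine interaction networks from literature: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condl)
```

## The problem

Fever is among the most common adverse events of vaccination, and the gene
interaction machinery behind it — endogenous pyrogens such as IL-1, IL-6
and TNF, their receptors, and the downstream arachidonic-acid pathway — is
scattered across hundreds of thousands of abstracts. `condl` implements a
centrality- and ontology-based literature mining pipeline that turns an
abstract corpus into gene–gene and gene–vaccine interaction networks and
then prioritizes the genes in them. The stages are:

1. **Corpus handling** — documents are split into sentences; literature
   subsets are selected by term matchers (generic "vaccine" variants, or
   the leaf terms of a vaccine ontology).
2. **Entity tagging** — dictionary- and rule-based recognition of gene
   mentions normalized to official symbols, and of vaccine mentions via an
   OBO ontology with transitive `is_a` closure.
3. **Candidate selection** — sentences containing an interaction keyword
   and two distinct entities (two genes, or a gene and a vaccine).
4. **Path classification** — the shortest dependency path between the two
   entity head tokens is scored by an SVM with an edit-distance kernel;
   pairs with positive confidence become interactions.
5. **Network analysis** — assembly into undirected evidence-carrying
   networks; degree, eigenvector, closeness and betweenness centrality;
   top-k comparison between networks; gene-set over-representation; and
   overlap with an external protein–protein interaction (PPI) network,
   including indirect-interaction hypothesis generation.

## Entity tagging rules

The tagger is deliberately dictionary- and rule-based (no learned NER), so
its behaviour is fully auditable:

* Surface normalization lowercases, spells out Greek letters (γ → gamma),
  and collapses hyphen/whitespace runs, so `IFN-γ`, `IFN gamma` and
  `IFNgamma` share one index key; hyphenated symbol forms are additionally
  indexed without the hyphen (`IL-6` ⇔ `IL6`).
* Matching runs left to right over alphanumeric token boundaries and the
  **longest indexed match wins**, so "BCG vaccine" absorbs the bare token
  "vaccine". Mentions can therefore never overlap.
* **Case rule**: surfaces of ≤ 2 characters must match an indexed form
  case-sensitively. This keeps two-letter official symbols usable while
  refusing common words ("as", "in", "ab").
* **Ambiguity rule**: a surface mapping to more than one official symbol is
  dropped unless it *is* one of those symbols verbatim. This trades recall
  for precision, which is the sensible direction when millions of
  candidate sentences are available.
* Vaccine tagging uses the leaf terms under the configured root (the
  "specific vaccine names at the bottom of the hierarchy"); interior terms
  are not tagged by default. Generic mentions come from a configurable
  surface-variant list (`vaccine`, `vaccination`, ...). Only transitive
  `is_a` closure is implemented; OWL reasoning over logical definitions is
  out of scope.

## Sentence splitting

Sentences are split at `.`, `?` or `!` followed by whitespace and an
uppercase letter or digit, guarded by a configurable abbreviation list
("E.", "sp.", "et al.", "Fig.", "vs.", ...). The title is one sentence
unless it contains sentence-final punctuation. Offsets are 0-based
half-open into `title + "\n" + abstract`, and every sentence is an exact
slice of its source — an invariant the tests enforce, since all downstream
mention spans are sentence-local.

## Dependency paths and their encoding

Parses are consumed as CoNLL-U (the package does not parse text itself).
For a candidate pair the unique tree path between the two mention head
tokens is extracted. A mention aligns to the overlapped token whose
syntactic head lies outside the mention (the phrase head), falling back to
the rightmost overlapped token — the head-final bias of English noun
phrases. Node tokens are lowercase lemmas (form when the lemma column is
`_`), with the endpoints replaced by `ENTITYA`/`ENTITYB` and any other
tagged entity on the path by `ENTITYX`; edge tokens are dependency
relations suffixed with a traversal direction marker (`<` toward the head,
`>` toward the dependent). So "IL6 activates STAT3" yields

```
ENTITYA nsubj< activate dobj> ENTITYB
```

and the reverse path is the reversed sequence with markers flipped. The
placeholders make paths comparable across sentences regardless of which
genes are involved.

Interaction keywords are matched at token boundaries after light stemming:
one terminal inflection among "ing", "ed", "es", "s" is stripped when the
stem keeps ≥ 4 characters (never stripping the "s" of a "ss" ending), then
a trailing "e" is removed. This maps sentence tokens ("induced",
"activates", "suppresses") and base-form keyword entries ("induce",
"activate", "suppress") to a single canonical stem; a bare suffix-strip
rule would leave "induced"/"induce" unmatched. A packaged default list of
~50 stems (bind, activate, induce, inhibit, ...) is user-replaceable.

## The edit-distance kernel SVM

Paths are compared by token-level Levenshtein distance $d$ (unit
insert/delete/substitute over whole tokens), and similarity by

$$k(x, y) = \exp(-\gamma\, d(x, y)), \qquad \gamma > 0 .$$

This form is bounded in $(0, 1]$, has $k(x,x)=1$, decays smoothly with
edit distance, and has a single hyperparameter. Defaults are
$\gamma = 0.25$ and $C = 1$; both matter mainly through the margin, and the
packaged defaults are deliberately mild because the decision threshold is
fixed at 0 ("positive confidence scores" define edges) rather than tuned.

Edit-distance kernels are not guaranteed positive semidefinite. The
training Gram matrix is therefore spectrally repaired: eigenvalues below
$-10^{-9}$ trigger clipping of all negative eigenvalues to zero and
reconstitution, and the model records a `psdRepaired` flag. Test-time
scores always use the raw kernel — repair is a training-side device, and
the decision function is the standard expansion
$f(x) = \sum_i \alpha_i y_i\, k(s_i, x) + b$ over the support sequences.
The dual problem itself is solved by `kernlab::ksvm` (C-classification on
a precomputed kernel matrix); the solver's internal class orientation is
calibrated against the training labels so that positive labels always map
to positive decision values, deterministically given the seed and data
order.

## Networks, centrality, and comparison

Positively scored pairs aggregate into a simple undirected graph: one edge
per unordered pair, carrying the set of supporting `(document, sentence)`
evidence, its count (rendered as edge thickness in viewers), and the
maximum SVM score. Self-pairs are dropped; generic vaccine mentions share
the single node `"vaccine"`. Sub-networks restrict the evidence to a
document subset, so a sub-network's edges are always a subset of the full
network's. Edges are undirected: the keyword vocabulary contains
directional relations, but the network-level analyses are orientation-free,
and direction survives inside the evidence records.

Four centralities are computed on the full graph:

* **degree** — raw edge count;
* **eigenvector** — power iteration, uniform positive start,
  L2-normalized, converged when successive iterates differ by
  < 10⁻¹⁰. The iteration runs on $A + I$: on bipartite graphs the
  adjacency's spectrum is symmetric and plain power iteration oscillates
  with period 2, whereas the shift leaves the eigenvectors untouched and
  makes the dominant one unique on any connected graph;
* **closeness** — within a component of size $n_c$,
  $(n_c-1)/\sum d$ scaled by $(n_c-1)/(N-1)$ (the Wasserman–Faust
  correction). Literature networks are routinely disconnected, and the
  correction keeps scores comparable across components while isolated
  nodes score 0;
* **betweenness** — unnormalized Brandes accumulation, endpoints excluded,
  each unordered pair counted once. Only ranks are consumed downstream, so
  normalization would be cosmetic.

Ranks order by descending score with ties broken by node id ascending — a
deterministic permutation — and vaccine nodes are excluded from ranking by
default (gene prioritization), configurably. The two-network comparison
collects the genes ranked in the top k (default 10) by *at least one*
measure in each network and partitions them into `both` / `a_only` /
`b_only`; the printable table shows per-metric ranks with `---` beyond k.

## Enrichment

Over-representation uses the upper-tail hypergeometric probability
$P(X \ge k)$ for query size $n$, term size $K$, background $N$; the
default **EASE** variant substitutes $\max(k-1, 0)$, a deliberately
conservative score, and terms with overlap $k < 2$ are skipped. The
background defaults to the union of all annotated genes (logged in the
output) since externally curated backgrounds vary by database snapshot.
Benjamini–Hochberg correction is applied across tested terms at
$\alpha = 0.05$. The tail comes from `phyper` and BH from `p.adjust`; the
tests verify both against exhaustive draw enumeration and the hand-applied
step-up formula.

## PPI overlap and indirect hypotheses

An external PPI edge list (HPRD-style TSV) is normalized through the same
gene lexicon, deduplicated and stripped of self-interactions. By default
the comparison is restricted to PPI edges among the literature network's
genes — the comparison of interest is "which of *our* genes' interactions
are independently known", not HPRD's global content. The merged network
tags every edge `literature`, `ppi`, or `both`. For an anchor pair carried
by both sources, indirect hypotheses are the cross product of the
literature-only neighbors of one anchor gene with the PPI-only neighbors
of the other (both orientations, all four genes distinct): if x–a is seen
in text, a–b in both, and b–y in the PPI database, x and y plausibly
interact through the a–b bridge.

## The synthetic bundle: what it does and does not emulate

`generateFixtures()` produces a complete, self-consistent input bundle —
corpus TSV, one hand-authored CoNLL-U parse per sentence, gene lexicon,
vaccine ontology (root → "live attenuated vaccine" → 5 leaf vaccines),
keyword list, labeled training paths, planted truth edges, a PPI list
overlapping the truth, and a GMT annotation file. Positive sentences
instantiate six interaction templates (active, passive, "interacts with",
prepositional adjunct, two adverbial variants) over six verbs; negative
sentences are co-occurrence without a keyword ("X and Y were measured"),
keyword without a pair, keyword with a *non-interacting* pair ("X
activates metabolism in Y cells" — the entity pair straddles the verb but
the path detours through the object NP), and entity-free filler. Parses
are template-level skeletons validated at generation time (single root, no
dangling heads, acyclic), not parser output — that keeps the bundle
deterministic and dependency-free. Entity slots expand to multi-token
phrases with the rightmost token as phrase head, exercising the
mention-to-token alignment rule; the lexicon plants hyphen variants, a
two-letter symbol, and one ambiguous synonym to exercise the tagging rules.

Default conditions: 200 documents × 3 sentences (the first sentence is the
title), 30 genes, 5 leaf vaccines, 40% interaction-template sentences, a
balanced 120-path training set, seed 42. These sizes keep the full
pipeline, including training and scoring, to roughly half a minute while
leaving several hundred candidate pairs — enough for the planted-recovery
evaluation to be meaningful.

What passing on this bundle shows: the plumbing is watertight — tagging,
alignment, path extraction, classification and assembly compose without
losing or inventing pairs, and the classifier separates path shapes it was
trained on. What it does not show: performance on real abstracts, whose
sentence structure, anaphora, gene-name ambiguity and parse errors are far
richer than six templates. Real-corpus figures (recall/precision of the
tagging stage, network sizes) are properties of external resources and are
not reproduced here.

## Numerical and design choices

* Hypergeometric tails use `phyper` on a shifted boundary
  (`phyper(k - 1, ..., lower.tail = FALSE)`), exact for the integer
  arguments used; no continuity tricks.
* Gram repair threshold $10^{-9}$; post-repair minimum eigenvalue is
  asserted ≥ $-10^{-9}$ in the tests.
* GraphML round-trips are exact for structure, ids, tags and evidence
  strings; edge scores are serialized as doubles at ~15 significant
  digits, so network equality is checked with an absolute score tolerance
  of $10^{-9}$.
* Power iteration caps at $10^5$ iterations and reports the iterate gap on
  non-convergence rather than returning a stale vector.
* Evaluation conventions for empty denominators: no predictions and no
  truth counts as perfect (1.0); predictions against empty truth give
  precision 0; empty predictions against nonempty truth give recall 0.
* Whether interactions are deduplicated per sentence or per abstract is an
  open modelling choice; per-sentence evidence is used here, and the edge
  attribute `n_sentences` preserves the multiplicity.
* Mention → token alignment ties resolve to the rightmost token; rank ties
  resolve by node id; both choices exist purely to make every output
  deterministic and are exercised by tests.

## Known limitations

* No coreference, no cross-sentence pairs, no abbreviation-definition
  linking ("tumor necrosis factor (TNF)"), no learned NER.
* The package consumes parses; it does not produce them. Garbage parses
  yield garbage paths.
* The kernel is a single edit-distance similarity; composite path kernels
  (e.g. mixing lemma, POS and relation channels) are out of scope.
* Edge direction, probability calibration of SVM scores, and
  statistically pruned edge weights are deliberately not implemented.
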