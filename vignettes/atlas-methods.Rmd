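---
title: "Building and evaluating a literature co-occurrence atlas of gene/cell-type relations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and evaluating a literature co-occurrence atlas of gene/cell-type relations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litatlas)
library(data.table)
```

## The problem and the model

Manual cell type annotation in single-cell RNA-seq relies on curated marker
databases that lag behind the literature. `litatlas` instead mines
pre-computed named-entity annotations of articles: whenever a normalised
gene concept and a normalised cell-type concept are mentioned in the same
article, that article contributes evidence for the pair. Aggregated over a
corpus, each (gene, cell type) pair carries two counts — the number of
distinct supporting articles $c_{pmid}$ and the total co-occurrence weight
$c_{total}$ — and is ranked by

$$\mathrm{score} = \log_{10}(c_{pmid}) \cdot \log_{10}(c_{total}).$$

Both factors grow with literature support, but logarithmically, so a
thousand-article term does not drown a fifty-article term; a pair supported
by a single article scores 0. The package also implements an aggregated
TF–IDF comparator ($c_{total} \cdot \log_{10}(D / c_{pmid})$ by default,
with log-tf and smoothed-idf variants selectable) to make the qualitative
contrast inspectable: for fixed $c_{total}$, TF–IDF *decreases* with
document spread while the atlas score increases. Because the published
presentation convention rounds scores to two decimals with
round-half-to-even, computation and display are separated
(`relation_score()` vs `format_score()`).

## Pipeline assumptions and parameters

* **NER is input, not a component.** Articles arrive already annotated
  (PubTator blocks or line-delimited JSON records); the package only
  normalises, filters and aggregates. Mention offsets are 0-based
  half-open over `title\nabstract` — the formats do not fix a convention,
  so one is chosen and applied consistently by both readers and writers.
  All mentions are weighted uniformly; no section provenance is recorded.
* **Catalogue filtering.** Only mentions whose concept id is in the gene or
  cell-type catalogue survive (`filter_mapped_mentions()`); cell lines and
  other entity classes are dropped. Free-text resolution is
  case-insensitive and exact — no stemming, no fuzzy matching — and an
  ambiguous surface form is returned as *unmapped* rather than guessed,
  because the annotator's normalised id is the primary key. Catalogues are
  offline TSVs behind a small resolver surface, so a live registry lookup
  could be slotted in without touching the pipeline.
* **Per-article co-occurrence weight** is not fixed by the aggregate counts
  alone, so it is pluggable: `min(gene mentions, cell mentions)` (default —
  bounds inflation from one hyper-mentioned entity), `product`, or
  `binary`. The deployment filter defaults to `min_pmids = 3` (the
  published production threshold) and `min_total = 1` (unstated; the
  weakest value that keeps the count invariants).
* **Store.** The environment provides no embedded SQL engine, so the
  production store is a schema-versioned directory of TSV tables
  (evidence, processed-article log, metadata). Ingestion is idempotent per
  pmid and batch-atomic; aggregation is order-invariant and associative
  under `merge_incremental()`, which refuses merges with overlapping
  article provenance.
* **Query semantics.** One result row per (resolved concept, counterpart)
  pair; ranking is total and deterministic: score desc, then $c_{pmid}$
  desc, then counterpart name asc. Multi-marker annotation combines
  per-gene scores per cell type with `sum` by default (rewards breadth and
  strength; `mean` and `count` selectable). Graph nodes are weighted by
  the max incident edge score (sum selectable) — "scaled by score" is
  ambiguous for nodes, so the choice is explicit. Gene–gene co-mention
  edges are out of the store schema and not generated.

## Ontology distance

Cell-type relatedness is measured on the `is_a` DAG of a Cell Ontology
style OBO file: the distance between two terms is the shortest-path length
treating every `is_a` edge as undirected with unit cost. This reproduces
the intended semantics exactly — parent/child 1, siblings 2 (up and back
down), identity 0 — and extends to arbitrary pairs; multiple-parent terms
take the shorter chain. A uniform-cost search restricted to
common-ancestor ("hourglass") paths would agree on all the documented
examples; the unrestricted undirected metric is used because it is the
minimal interpretation that matches them. Only `is_a` is consulted
(`part_of` etc. are ignored), obsolete terms are excluded, and
disconnected pairs return `NA` rather than a sentinel — the evaluation
layer decides their fate (`exclude` by default, `penalize(k)` optional).

```{r}
ont <- anucleate_cell_ontology()
term_distance(ont, "CL:0002153", "CL:0000233")  # siblings
```

## Marker-gene evaluation

The benchmark mirrors the field's recall-oriented comparison against a
curated marker database. Per expression cluster, the top $n = 50$ DEGs are
selected by the one-versus-rest mean-expression ratio
$(\mu_{c} + \epsilon) / (\bar\mu_{\neg c} + \epsilon)$ with pseudocount
$\epsilon = 10^{-9}$ (unstated upstream; small enough never to reorder
non-degenerate ratios, ties broken alphabetically for determinism). Each
gene is looked up in both databases; the top-1 hit's ontology distance to
the reference cell type is recorded per database, and the combined
distance is the minimum over the matched databases — a gene matched in
only one database keeps that database's singular top-1 distance.
Curated databases carry no co-occurrence counts, so their internal rank is
an interpretation: file order by default, marker count optionally.
Summaries per reference cell type report the mean ± sample σ (n−1) of
either the per-gene difference $d_A - d_B$ over jointly matched genes or
the combined distance over all matched genes; both are emitted because a
difference plot and an absolute plot answer different questions. Match
categories (A-only / both / B-only / neither) always partition the gene
list, and the database-extension fraction is `a_only / (a_only + neither)`.

## The synthetic world

Every stage is testable offline through seeded generators. The corpus
generator plants each synthetic gene on one cell type; in each article the
co-mention count of a pair is Poisson with mean `base_rate` (0.05) for
planted pairs and `noise_rate` (0.001) for background pairs, over
`n_articles` = 400 articles, 40 genes and 8 cell types. These defaults
emulate a focused literature: a planted relation gathers ~20 distinct
supporting articles (safely above the 3-article deployment filter) while
background pairs mostly fall below it, and article-level cross-talk (a
gene co-occurring with another gene's cell type in the same article) stays
an order of magnitude weaker than the planted signal. What the generator
deliberately does *not* emulate: real English text, annotator error modes,
redundant synonyms across articles, or the heavy-tailed popularity of real
genes — so a green recovery test establishes that the pipeline's counting,
filtering and ranking are correct, not that any particular recall would be
reached on real literature. The generator also writes every interchange
format (PubTator, record JSON, catalogue/marker/expression TSV, OBO) so
the I/O layers are exercised end-to-end, and keeps its own per-pair
bookkeeping so conservation (evidence in = evidence out) is checkable
against an independent count.

The expression generator elevates each cluster's planted markers by a
fold-`effect` (default 5) over a uniform baseline; `effect = 1` is the
null world in which DEG selection must not systematically recover
markers. The toy ontology generator grows a rooted DAG (each later term
picks 1–2 earlier parents), acyclic by construction, used for the
property tests of the distance metric against a breadth-first-search
oracle.

## Numerical and degenerate-input choices

* Scores are kept at full precision; only display rounds (half-to-even).
* `normalize_scores()` maps an all-equal score set to 0 under `minmax`.
* Duplicate pmids keep the first occurrence and warn — deterministic
  ingestion beats silent overwrites.
* An unresolvable query term returns an empty, annotated result rather
  than an error, matching interactive search semantics; a malformed
  annotation line skips that line, not the document.
* `select_top_degs()` with `n` above the gene count returns all genes
  with a note; a single-record cell-type summary reports a 0-width band
  with an explicit `single_record` flag rather than NA arithmetic.

## Known limitations

The atlas is built from co-occurrence, not assertion: a co-mention does
not guarantee a marker relation, and negative statements count as
support. No species filtering is applied. The evaluation can only measure
recall-style agreement, since neither database enumerates all true
relations. Corpus-scale behaviour (millions of articles) is outside the
test envelope; the store is a flat-file stand-in for an embedded database
and would be the first component to swap at scale.
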