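library(data.table)

# tiny two-concept catalogues shared across tests
tiny_gene_catalog <- function() {
  concept_catalog(data.table(
    cui = c("G1", "G2"),
    canonical_name = c("alpha-1-B glycoprotein", "Wilms tumor 1"),
    abbreviation = c("A1BG", "WT1"),
    gene_type = c("protein-coding", "protein-coding"),
    synonyms = c("A1B|ABG", "WT-1")), "gene")
}

tiny_cell_catalog <- function() {
  concept_catalog(data.table(
    cui = c("C1", "C2", "C3"),
    canonical_name = c("B cell", "T cell", "podocyte"),
    abbreviation = "", gene_type = "",
    synonyms = c("B lymphocyte", "T lymphocyte", "")), "cell_type")
}

# one article with a mix of mapped/unmapped mentions
mixed_article <- function(pmid = 1L) {
  annotated_article(pmid, mention_table(
    surface_text = c("A1BG", "UNKNOWN1", "B cell", "HeLa"),
    entity_class = c("gene", "gene", "cell_type", "other"),
    concept_id = c("G1", "GX", "C1", NA),
    span_start = c(0L, 10L, 20L, 30L),
    span_end = c(4L, 18L, 26L, 34L)),
    title = "t", abstract = "a")
}

# build an in-memory store from articles (already mapped concept ids)
store_from <- function(articles, strategy = "min") {
  st <- atlas_store()
  ingest_articles(st, articles, strategy = strategy)
  st
}

# article with given per-concept mention counts
counted_article <- function(pmid, gene_counts = integer(),
                            cell_counts = integer()) {
  tokens <- c(rep(names(gene_counts), gene_counts),
              rep(names(cell_counts), cell_counts))
  classes <- c(rep("gene", sum(gene_counts)),
               rep("cell_type", sum(cell_counts)))
  n <- length(tokens)
  if (n == 0L) return(annotated_article(pmid))
  annotated_article(pmid, mention_table(
    surface_text = tokens, entity_class = classes, concept_id = tokens,
    span_start = seq(0L, by = 10L, length.out = n),
    span_end = seq(5L, by = 10L, length.out = n)))
}

# independent BFS oracle for undirected unit-cost distances
bfs_all_distances <- function(adj, source) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[source] <- 0L
  frontier <- source
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

ontology_adjacency <- function(ont) {
  ids <- ontology_ids(ont)
  adj <- rep(list(integer()), length(ids))
  if (nrow(ont$edges)) {
    ci <- match(ont$edges$child, ids)
    pi <- match(ont$edges$parent, ids)
    for (k in seq_along(ci)) {
      adj[[ci[k]]] <- c(adj[[ci[k]]], pi[k])
      adj[[pi[k]]] <- c(adj[[pi[k]]], ci[k])
    }
  }
  adj
}

expect_same_rows <- function(a, b) {
  keys <- intersect(names(a), names(b))
  expect_equal(
    as.data.frame(data.table::setorderv(as.data.table(a)[, ..keys], keys)),
    as.data.frame(data.table::setorderv(as.data.table(b)[, ..keys], keys)),
    ignore_attr = TRUE)
}
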