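# deployment fixture whose counts mirror the published A1BG example
demo_deployment <- function() {
  demo <- demo_corpus()
  arts <- lapply(demo$articles, filter_mapped_mentions,
                 gene_ids = catalog_ids(demo$gene_catalog),
                 cell_ids = catalog_ids(demo$cell_catalog))
  list(rows = aggregate_to_deployment(store_from(arts)), demo = demo)
}

test_that("gene query on the reference fixture returns the published order and scores", {
  fx <- demo_deployment()
  hits <- query_gene(fx$rows, "alpha-1-B glycoprotein",
                     fx$demo$gene_catalog, fx$demo$cell_catalog)
  expect_equal(hits$name, c("B cell", "Platelet", "Enucleate erythrocyte",
                            "T cell", "Neutrophil"))
  expect_equal(format_score(hits$score), c(4.79, 4.17, 4.15, 3.93, 2.94))
  expect_equal(hits$c_pmid, c(110L, 64L, 67L, 73L, 35L))
  # provenance: pmids length equals c_pmid, scores recompute from own counts
  expect_equal(lengths(hits$pmids), hits$c_pmid)
  expect_equal(hits$score, relation_score(hits$c_pmid, hits$c_total))
})

test_that("cell query transposes the fixture and honours the gene-type filter", {
  fx <- demo_deployment()
  hits <- query_cell(fx$rows, "B cell", fx$demo$gene_catalog,
                     fx$demo$cell_catalog)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$name, "alpha-1-B glycoprotein")
  expect_equal(format_score(hits$score), 4.79)
  filtered <- query_cell(fx$rows, "B cell", fx$demo$gene_catalog,
                         fx$demo$cell_catalog,
                         gene_type_filter = "pseudogene")
  expect_equal(nrow(filtered), 0L)
})

test_that("score cutoff, limit and unresolved terms behave per contract", {
  fx <- demo_deployment()
  gc <- fx$demo$gene_catalog; cc <- fx$demo$cell_catalog
  expect_equal(nrow(query_gene(fx$rows, "A1BG", gc, cc,
                               score_cutoff = 99)), 0L)
  expect_equal(nrow(query_gene(fx$rows, "A1BG", gc, cc, limit = 2)), 2L)
  none <- query_gene(fx$rows, "no-such-gene", gc, cc)
  expect_equal(nrow(none), 0L)
  expect_match(attr(none, "resolution_note"), "unresolved")
})

test_that("random-store rankings equal a brute-force sort with the documented tie rules", {
  set.seed(66)
  truth <- synthetic_truth(n_genes = 15, n_cells = 6, n_articles = 150,
                           base_rate = 0.2, noise_rate = 0.05, seed = 66)
  corp <- generate_corpus(truth)
  cats <- truth_catalogs(truth)
  dep <- aggregate_to_deployment(store_from(corp$articles))
  for (g in sample(truth$gene_symbols, 6)) {
    hits <- query_gene(dep, g, cats$gene, cats$cell)
    cui <- resolve_query_term(g, cats$gene)$cui
    rows <- dep[gene_cui == cui]
    if (nrow(rows) == 0L) { expect_equal(nrow(hits), 0L); next }
    sc <- relation_score(rows$c_pmid, rows$c_total)
    nm <- catalog_record(cats$cell, rows$cell_cui)$canonical_name
    ord <- order(-sc, -rows$c_pmid, nm)
    expect_equal(hits$cui, rows$cell_cui[ord])
    expect_equal(hits$score, sc[ord])
  }
})

test_that("marker-list annotation reduces to query_gene for one gene and sums for two", {
  fx <- demo_deployment()
  gc <- fx$demo$gene_catalog; cc <- fx$demo$cell_catalog
  single <- annotate_marker_list(fx$rows, "A1BG", gc, cc)
  hits <- query_gene(fx$rows, "A1BG", gc, cc)
  expect_equal(single$cui, hits$cui)
  expect_equal(single$combined_score, hits$score)
  # two genes uniquely linked to one cell sum their scores
  rows <- data.table::data.table(
    gene_cui = c("G1", "G2"), cell_cui = "C1",
    c_pmid = c(10L, 20L), c_total = c(30L, 40L))
  gcat <- tiny_gene_catalog(); ccat <- tiny_cell_catalog()
  both <- annotate_marker_list(rows, c("A1BG", "WT1"), gcat, ccat)
  expect_equal(both$combined_score,
               sum(relation_score(c(10, 20), c(30, 40))))
  expect_equal(both$n_genes, 2L)
})

test_that("marker-list combination is permutation-invariant and rules differ as documented", {
  truth <- synthetic_truth(n_genes = 10, n_cells = 4, n_articles = 120,
                           base_rate = 0.25, noise_rate = 0.05, seed = 13)
  cats <- truth_catalogs(truth)
  dep <- aggregate_to_deployment(store_from(generate_corpus(truth)$articles))
  genes <- truth$gene_symbols[1:6]
  a <- annotate_marker_list(dep, genes, cats$gene, cats$cell)
  b <- annotate_marker_list(dep, rev(genes), cats$gene, cats$cell)
  expect_equal(a$cui, b$cui)
  expect_equal(a$combined_score, b$combined_score)
  cnt <- annotate_marker_list(dep, genes, cats$gene, cats$cell,
                              combine = "count")
  contrib <- attr(cnt, "contributions")
  expect_equal(cnt$combined_score,
               contrib[, .N, by = cui][match(cnt$cui, cui)]$N + 0)
})

test_that("co-occurrence graph: star shape, merged shared concepts, weight rules", {
  fx <- demo_deployment()
  gc <- fx$demo$gene_catalog; cc <- fx$demo$cell_catalog
  g <- build_cooccurrence_graph(fx$rows, "A1BG", gc, cc)
  expect_equal(igraph::vcount(g), 6L)   # gene + 5 cells
  expect_equal(igraph::ecount(g), 5L)
  expect_true(igraph::is_bipartite(
    igraph::set_vertex_attr(g, "type",
                            value = igraph::V(g)$class == "gene")))
  # gene node labelled by abbreviation, full name kept as detail
  v <- igraph::V(g)[igraph::V(g)$class == "gene"]
  expect_equal(v$label, "A1BG")
  expect_equal(v$full_name, "alpha-1-B glycoprotein")
  # node size-weight is the max incident edge score
  expect_equal(v$size_weight, max(igraph::E(g)$weight))
  # querying the gene and one of its cells merges on the shared concepts
  g2 <- build_cooccurrence_graph(fx$rows, c("A1BG", "B cell"), gc, cc)
  expect_equal(igraph::vcount(g2), 6L)
  expect_equal(igraph::ecount(g2), 5L)
})

test_that("graph node/edge sets equal the brute-force union of per-term subgraphs", {
  truth <- synthetic_truth(n_genes = 12, n_cells = 5, n_articles = 150,
                           base_rate = 0.25, noise_rate = 0.05, seed = 21)
  cats <- truth_catalogs(truth)
  dep <- aggregate_to_deployment(store_from(generate_corpus(truth)$articles))
  terms <- c(truth$gene_symbols[1:3], truth$cell_names[2])
  g <- build_cooccurrence_graph(dep, terms, cats$gene, cats$cell)
  edges <- list()
  for (tm in terms) {
    gh <- query_gene(dep, tm, cats$gene, cats$cell)
    ch <- query_cell(dep, tm, cats$gene, cats$cell)
    if (nrow(gh)) edges[[length(edges) + 1L]] <-
        data.table::data.table(g = gh$query_cui, c = gh$cui)
    if (nrow(ch)) edges[[length(edges) + 1L]] <-
        data.table::data.table(g = ch$cui, c = ch$query_cui)
  }
  brute <- unique(data.table::rbindlist(edges))
  expect_equal(igraph::ecount(g), nrow(brute))
  expect_setequal(igraph::V(g)$name, unique(c(brute$g, brute$c)))
  empty <- build_cooccurrence_graph(dep, "nonexistent", cats$gene,
                                    cats$cell)
  expect_equal(igraph::vcount(empty), 0L)
})

test_that("graph export round-trips in both formats, including the empty graph", {
  fx <- demo_deployment()
  g <- build_cooccurrence_graph(fx$rows, "A1BG", fx$demo$gene_catalog,
                                fx$demo$cell_catalog)
  for (fmt in c("graphml", "node-link-json")) {
    f <- withr::local_tempfile(fileext = if (fmt == "graphml") ".graphml"
                               else ".json")
    export_graph(g, f, format = fmt)
    back <- import_graph(f, format = fmt)
    expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
    expect_equal(igraph::ecount(back), igraph::ecount(g))
    m <- match(igraph::V(g)$name, igraph::V(back)$name)
    expect_equal(igraph::V(back)$size_weight[m], igraph::V(g)$size_weight)
    expect_equal(sort(igraph::E(back)$weight), sort(igraph::E(g)$weight))
    f0 <- withr::local_tempfile(fileext = ".out")
    export_graph(igraph::make_empty_graph(directed = FALSE), f0,
                 format = fmt)
    expect_equal(igraph::vcount(import_graph(f0, format = fmt)), 0L)
  }
  expect_error(export_graph(g, tempfile(), format = "dot"))
})

test_that("hit tables export with the published column layout", {
  fx <- demo_deployment()
  hits <- query_gene(fx$rows, "A1BG", fx$demo$gene_catalog,
                     fx$demo$cell_catalog)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_hits(hits, f)
  tab <- data.table::fread(f, sep = "\t", colClasses = list(character = "score"))
  expect_equal(names(tab), c("name", "c_pmid", "c_total", "score", "pmids"))
  expect_equal(tab$score, c("4.79", "4.17", "4.15", "3.93", "2.94"))
})
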