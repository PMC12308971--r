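# small curated source fixture: two cells, three genes
tiny_curated <- function() {
  curated_marker_source(data.table::data.table(
    cell_cui = c("CL:1", "CL:1", "CL:2"),
    gene = c("g1", "g2", "g1")))
}

test_that("one-vs-rest DEG selection ranks planted genes first and breaks ties by name", {
  expr <- matrix(c(10, 0, 1, 1, 1, 1), nrow = 2, byrow = FALSE,
                 dimnames = list(c("A", "B"), c("g1", "g2", "g3")))
  degs <- select_top_degs(expr, n = 3)
  expect_equal(degs$A[1], "g1")
  uniform <- matrix(1, 2, 3, dimnames = list(c("A", "B"),
                                             c("gb", "ga", "gc")))
  expect_equal(select_top_degs(uniform, n = 3)$A, c("ga", "gb", "gc"))
  expect_message(all_back <- select_top_degs(uniform, n = 10), "exceeds")
  expect_length(all_back$A, 3L)
  expect_error(select_top_degs(uniform[1, , drop = FALSE]), "two clusters")
})

test_that("DEG selection recovers planted markers before non-markers (seeded)", {
  ex <- generate_expression_matrix(n_clusters = 4, n_genes = 40,
                                   markers_per_cluster = 5, effect = 10,
                                   seed = 19)
  degs <- select_top_degs(ex$expr, n = 5)
  for (cl in ex$cluster_names) {
    expect_setequal(degs[[cl]], ex$markers[[cl]])
  }
  # null case: effect 1 gives no systematic recovery
  null <- generate_expression_matrix(4, 40, 5, effect = 1, seed = 19)
  hit <- mean(unlist(lapply(null$cluster_names, function(cl)
    select_top_degs(null$expr, n = 5)[[cl]] %in% null$markers[[cl]])))
  expect_lt(hit, 0.6)
})

test_that("DEG ranking matches a brute-force ratio recomputation", {
  set.seed(33)
  expr <- matrix(stats::rexp(5 * 30), 5, 30,
                 dimnames = list(sprintf("cl%d", 1:5),
                                 sprintf("g%02d", 1:30)))
  degs <- select_top_degs(expr, n = 30, pseudocount = 1e-9)
  for (cl in rownames(expr)) {
    ratio <- (expr[cl, ] + 1e-9) /
      (colMeans(expr[setdiff(rownames(expr), cl), ]) + 1e-9)
    expect_equal(degs[[cl]],
                 colnames(expr)[order(-ratio, colnames(expr))])
  }
})

test_that("curated marker source ranks by file order or marker count", {
  src <- tiny_curated()
  expect_equal(rank_cells(src, "G1"), c("CL:1", "CL:2"))  # case-insensitive
  expect_equal(rank_cells(src, "g3"), character())
  by_count <- curated_marker_source(src$table[, .(cell_cui, gene)],
                                    rank_by = "marker_count")
  expect_equal(rank_cells(by_count, "g1"), c("CL:1", "CL:2"))
})

test_that("top1 distance measures the top hit against the reference", {
  ont <- anucleate_cell_ontology()
  src <- curated_marker_source(data.table::data.table(
    cell_cui = c("CL:0002153", "CL:0000233"), gene = c("gA", "gA")))
  hit <- top1_distance(src, ont, "gA", "CL:0002153")
  expect_equal(hit$top1, "CL:0002153")
  expect_equal(hit$distance, 0L)
  # top-1 is the reference's parent
  parent <- top1_distance(curated_marker_source(data.table::data.table(
    cell_cui = "CL:0000225", gene = "gB")), ont, "gB", "CL:0002153")
  expect_equal(parent$distance, 1L)
  none <- top1_distance(src, ont, "gZ", "CL:0000225")
  expect_true(is.na(none$top1) && is.na(none$distance))
  expect_error(top1_distance(src, ont, "gA", "CL:404"), "CL:404")
})

test_that("combined distance is the minimum over matched databases", {
  expect_equal(combined_distance(3L, 1L), 1L)
  expect_equal(combined_distance(NA_integer_, 2L), 2L)
  expect_equal(combined_distance(2L, NA_integer_), 2L)
  expect_true(is.na(combined_distance(NA_integer_, NA_integer_)))
  expect_error(combined_distance(NA_integer_, NA_integer_, strict = TRUE),
               "unmatched")
  set.seed(5)
  a <- sample(c(0:4, NA), 50, TRUE)
  b <- sample(c(0:4, NA), 50, TRUE)
  got <- combined_distance(a, b)
  oracle <- mapply(function(x, y) {
    v <- c(x, y)[!is.na(c(x, y))]
    if (length(v)) min(v) else NA_integer_
  }, a, b)
  expect_equal(got, oracle, ignore_attr = TRUE)
})

test_that("gene match categories partition the list and match set algebra", {
  db_a <- tiny_curated()
  db_b <- curated_marker_source(data.table::data.table(
    cell_cui = "CL:2", gene = c("g2", "g4")))
  cats <- categorize_gene_matches(c("g1", "g2", "g3"), db_a, db_b)
  expect_equal(cats, c(a_only = 1L, both = 1L, b_only = 0L, neither = 1L))
  expect_equal(sum(cats), 3L)
  empty <- categorize_gene_matches(character(), db_a, db_b)
  expect_equal(sum(empty), 0L)
  set.seed(17)
  for (rep in 1:5) {
    genes_a <- sample(sprintf("g%d", 1:20), 8)
    genes_b <- sample(sprintf("g%d", 1:20), 8)
    da <- curated_marker_source(data.table::data.table(cell_cui = "CL:1",
                                                       gene = genes_a))
    db <- curated_marker_source(data.table::data.table(cell_cui = "CL:1",
                                                       gene = genes_b))
    all_genes <- sprintf("g%d", 1:20)
    got <- categorize_gene_matches(all_genes, da, db)
    expect_equal(unname(got["a_only"]), length(setdiff(genes_a, genes_b)))
    expect_equal(unname(got["both"]), length(intersect(genes_a, genes_b)))
    expect_equal(unname(got["b_only"]), length(setdiff(genes_b, genes_a)))
    expect_equal(sum(got), 20L)
  }
})

test_that("database-extension arithmetic reproduces the published percentages", {
  # printed per-dataset category counts (atlas-only, both, curated-only,
  # neither) for the three benchmark datasets
  tab <- data.table::data.table(
    dataset = c("TM", "MCA", "PBMC"),
    a_only = c(134L, 548L, 274L), both = c(1619L, 3129L, 132L),
    b_only = c(757L, 375L, 4L), neither = c(240L, 7008L, 90L))
  ext <- tab$a_only / (tab$a_only + tab$neither)
  expect_equal(round(100 * ext, 2), c(35.83, 7.25, 75.27))
  expect_equal(round(ext[c(3, 1)], 2), c(0.75, 0.36))
  expect_equal(colSums(tab[, -1]),
               c(a_only = 956, both = 4880, b_only = 1136, neither = 7338))
})

test_that("evaluation records satisfy the combined-dominance invariant", {
  truth <- synthetic_truth(n_genes = 20, n_cells = 5, n_articles = 200,
                           base_rate = 0.1, noise_rate = 0.01, seed = 47)
  cats <- truth_catalogs(truth)
  dep <- apply_deployment_filter(
    aggregate_to_deployment(store_from(generate_corpus(truth)$articles)))
  ont <- truth_ontology(truth)
  db_a <- atlas_marker_source(dep, cats$gene, cats$cell)
  db_b <- curated_marker_source(curated_db_from_truth(truth, 0.6))
  rec <- evaluate_markers(truth$gene_symbols,
                          truth$cell_cuis[truth$planted], db_a, db_b, ont)
  expect_equal(nrow(rec), 20L)
  matched <- rec[!is.na(combined)]
  expect_true(all(matched$combined <= matched$dist_a, na.rm = TRUE))
  expect_true(all(matched$combined <= matched$dist_b, na.rm = TRUE))
  expect_true(all(rec[is.na(dist_a) & is.na(dist_b)][, is.na(combined)]))
  # mean combined <= each single-db mean over the jointly matched genes
  both <- rec[!is.na(dist_a) & !is.na(dist_b)]
  if (nrow(both)) {
    expect_lte(mean(both$combined), mean(both$dist_a))
    expect_lte(mean(both$combined), mean(both$dist_b))
  }
})

test_that("per-cell-type summaries compute mean and sample sigma", {
  rec <- data.table::data.table(
    gene = c("g1", "g2", "g3"), reference_cell = c("C", "C", "D"),
    top1_a = "x", top1_b = "y",
    dist_a = c(2L, 0L, 1L), dist_b = c(1L, 1L, NA_integer_),
    combined = c(1L, 0L, 1L))
  diff <- summarize_by_celltype(rec, "per_db_difference")
  expect_equal(diff[reference_cell == "C"]$mean, 0)     # (+1, -1)
  expect_equal(diff[reference_cell == "C"]$sigma, sqrt(2))
  expect_false("D" %in% diff$reference_cell)            # unmatched in b
  comb <- summarize_by_celltype(rec, "combined")
  expect_equal(comb[reference_cell == "D"]$mean, 1)
  expect_equal(comb[reference_cell == "D"]$sigma, 0)    # degenerate n = 1
  expect_true(comb[reference_cell == "D"]$single_record)
  # formula oracle on simulated records
  set.seed(31)
  sim <- data.table::data.table(
    gene = sprintf("g%d", 1:60),
    reference_cell = sample(c("C1", "C2", "C3"), 60, TRUE),
    top1_a = "x", top1_b = "y",
    dist_a = sample(0:3, 60, TRUE), dist_b = sample(0:3, 60, TRUE))
  sim[, combined := pmin(dist_a, dist_b)]
  s <- summarize_by_celltype(sim, "per_db_difference")
  for (cl in s$reference_cell) {
    v <- sim[reference_cell == cl, as.numeric(dist_a - dist_b)]
    expect_equal(s[reference_cell == cl]$mean, mean(v))
    expect_equal(s[reference_cell == cl]$sigma, stats::sd(v))
  }
})

test_that("evaluation report writes TSV records and a JSON summary", {
  rec <- data.table::data.table(
    gene = "g1", reference_cell = "C", top1_a = "C", top1_b = NA_character_,
    dist_a = 0L, dist_b = NA_integer_, combined = 0L)
  cats <- c(a_only = 1L, both = 0L, b_only = 0L, neither = 0L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rec, cats, tsv, js)
  expect_equal(data.table::fread(tsv)$gene, "g1")
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$categories$a_only, 1L)
  expect_equal(parsed$combined$mean, 0)
})
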