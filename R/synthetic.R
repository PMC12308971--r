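#' Define a synthetic corpus ground truth
#'
#' The stated world for end-to-end tests: each synthetic gene is planted on
#' one cell type; in every article the co-mention count of a (gene, cell)
#' pair is drawn independently with mean `base_rate * association` for
#' planted pairs and `noise_rate` for background pairs (a Poisson law; the
#' contract is on the means and on byte-for-byte determinism under `seed`).
#' Defaults emulate a focused literature: a planted pair is co-mentioned in
#' roughly 5% of articles, background co-mentions are 50x rarer, and 400
#' articles give planted relations on the order of 20 supporting articles —
#' comfortably above the deployment filter of 3 distinct articles.
#'
#' @param n_genes,n_cells,n_articles World dimensions.
#' @param base_rate Per-article mean co-mention count of a planted pair.
#' @param multiplier Association-matrix multiplier for planted pairs.
#' @param noise_rate Per-article mean co-mention count of background pairs.
#' @param seed Integer seed fixing the planted map and the corpus.
#' @return Object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(n_genes = 40L, n_cells = 8L, n_articles = 400L,
                            base_rate = 0.05, multiplier = 1,
                            noise_rate = 0.001, seed = 1L) {
  stopifnot(n_genes >= 1L, n_cells >= 1L, n_articles >= 1L,
            base_rate >= 0, multiplier >= 0, noise_rate >= 0)
  set.seed(seed)
  planted <- sample.int(n_cells, n_genes, replace = TRUE)
  association <- matrix(0, n_genes, n_cells)
  association[cbind(seq_len(n_genes), planted)] <- multiplier
  gene_cuis <- sprintf("GENE:%04d", seq_len(n_genes))
  cell_cuis <- sprintf("CL:%07d", 1000000L + seq_len(n_cells))
  structure(list(
    n_genes = n_genes, n_cells = n_cells, n_articles = n_articles,
    base_rate = base_rate, multiplier = multiplier,
    noise_rate = noise_rate, seed = seed,
    planted = planted, association = association,
    lambda = base_rate * association + noise_rate,
    gene_cuis = gene_cuis, cell_cuis = cell_cuis,
    gene_symbols = sprintf("SGENE%d", seq_len(n_genes)),
    gene_names = sprintf("synthetic gene %d protein", seq_len(n_genes)),
    cell_names = sprintf("synthetic cell type %d", seq_len(n_cells))),
    class = "synthetic_truth")
}

#' Generate an annotated corpus from a synthetic truth
#'
#' Draws per-article co-mention counts, materialises them as annotated
#' articles (gene and cell-type mentions with consistent text offsets over
#' title + abstract), and records the generator's own bookkeeping: expected
#' evidence per pair under the min/product/binary strategies computed
#' directly from the drawn mention counts, for conservation checks against
#' the ingestion pipeline.
#'
#' @param truth A [synthetic_truth()].
#' @param first_pmid pmid of the first article (consecutive after it).
#' @return `list(articles =, bookkeeping =)`; bookkeeping holds
#'   `evidence_min`, `evidence_product`, `evidence_binary` (aggregated
#'   per-pair `c_pmid`/`c_total` tables), and `n_mentions`.
#' @export
generate_corpus <- function(truth, first_pmid = 100001L) {
  set.seed(truth$seed)
  A <- truth$n_articles; G <- truth$n_genes; C <- truth$n_cells
  counts <- array(stats::rpois(A * G * C,
                               rep(as.vector(truth$lambda), each = A)),
                  dim = c(A, G, C))
  gm <- apply(counts, c(1, 2), sum)   # article x gene mention counts
  cm <- apply(counts, c(1, 3), sum)   # article x cell mention counts
  articles <- vector("list", A)
  book <- list()
  for (a in seq_len(A)) {
    pmid <- first_pmid + a - 1L
    gidx <- which(gm[a, ] > 0L)
    cidx <- which(cm[a, ] > 0L)
    tokens <- c(rep(truth$gene_symbols[gidx], gm[a, gidx]),
                rep(truth$cell_names[cidx], cm[a, cidx]))
    classes <- c(rep("gene", sum(gm[a, gidx])),
                 rep("cell_type", sum(cm[a, cidx])))
    ids <- c(rep(truth$gene_cuis[gidx], gm[a, gidx]),
             rep(truth$cell_cuis[cidx], cm[a, cidx]))
    title <- sprintf("Synthetic article %d", pmid)
    abstract <- paste(tokens, collapse = " ")
    mentions <- if (length(tokens)) {
      width <- nchar(tokens)
      end <- nchar(title) + 1L + cumsum(width + 1L) - 1L  # 0-based half-open
      mention_table(tokens, classes, ids, end - width, end)
    } else mention_table()
    articles[[a]] <- annotated_article(pmid, mentions, title = title,
                                       abstract = abstract)
    if (length(gidx) && length(cidx)) {
      pairs <- data.table::CJ(g = gidx, c = cidx)
      book[[length(book) + 1L]] <- data.table::data.table(
        gene_cui = truth$gene_cuis[pairs$g],
        cell_cui = truth$cell_cuis[pairs$c],
        pmid = pmid,
        w_min = pmin(gm[a, pairs$g], cm[a, pairs$c]),
        w_product = gm[a, pairs$g] * cm[a, pairs$c],
        w_binary = 1L)
    }
  }
  ev <- if (length(book)) data.table::rbindlist(book) else
    data.table::data.table(gene_cui = character(), cell_cui = character(),
                           pmid = integer(), w_min = integer(),
                           w_product = integer(), w_binary = integer())
  agg_by <- function(col) {
    out <- ev[, .(c_pmid = data.table::uniqueN(pmid),
                  c_total = sum(.SD[[1]])),
              by = .(gene_cui, cell_cui), .SDcols = col]
    data.table::setorder(out, gene_cui, cell_cui)[]
  }
  list(articles = articles,
       bookkeeping = list(evidence_min = agg_by("w_min"),
                          evidence_product = agg_by("w_product"),
                          evidence_binary = agg_by("w_binary"),
                          n_mentions = sum(gm) + sum(cm)))
}

#' Concept catalogues for a synthetic truth
#'
#' @param truth A [synthetic_truth()].
#' @return `list(gene =, cell =)` of `concept_catalog` objects; gene
#'   records carry symbol abbreviations and a protein-coding gene type,
#'   cell records a shorthand synonym.
#' @export
truth_catalogs <- function(truth) {
  gene <- data.table::data.table(
    cui = truth$gene_cuis, canonical_name = truth$gene_names,
    abbreviation = truth$gene_symbols, gene_type = "protein-coding",
    synonyms = "")
  cell <- data.table::data.table(
    cui = truth$cell_cuis, canonical_name = truth$cell_names,
    abbreviation = "", gene_type = "",
    synonyms = sprintf("SCT%d", seq_len(truth$n_cells)))
  list(gene = concept_catalog(gene, "gene"),
       cell = concept_catalog(cell, "cell_type"))
}

#' Toy ontology over the synthetic cell types
#'
#' A minimal is_a hierarchy: one root term with every synthetic cell type
#' as a direct subclass, so identical terms score 0 and any two distinct
#' cell types are siblings at distance 2.
#'
#' @param truth A [synthetic_truth()].
#' @return An `ontology_graph`.
#' @export
truth_ontology <- function(truth) {
  root <- "CL:0000000"
  terms <- data.table::data.table(
    id = c(root, truth$cell_cuis),
    name = c("cell", truth$cell_names))
  edges <- data.table::data.table(child = truth$cell_cuis, parent = root)
  ontology_graph(terms, edges)
}

#' Curated marker-database stand-in from a synthetic truth
#'
#' Samples a fraction of the planted (gene, cell) associations into the
#' two-column curated-database format, emulating an independently curated
#' marker list with partial coverage.
#'
#' @param truth A [synthetic_truth()].
#' @param coverage Fraction of planted pairs included.
#' @param seed Seed for the coverage sample.
#' @return `data.table` with columns `cell_cui`, `gene` (gene symbol).
#' @export
curated_db_from_truth <- function(truth, coverage = 0.8,
                                  seed = truth$seed + 1L) {
  set.seed(seed)
  keep <- sort(sample.int(truth$n_genes,
                          max(1L, round(coverage * truth$n_genes))))
  data.table::data.table(cell_cui = truth$cell_cuis[truth$planted[keep]],
                         gene = truth$gene_symbols[keep])
}

#' Generate a random rooted is_a DAG
#'
#' Term `i > 1` receives 1..`max_parents` parents drawn from the earlier
#' terms, so the graph is acyclic by construction and connected through the
#' root.
#'
#' @param n_terms Number of terms (>= 1).
#' @param max_parents Maximum parents per term.
#' @param seed Integer seed.
#' @param ids Optional term ids (default `TOY:0001...`).
#' @return An `ontology_graph`.
#' @export
generate_toy_ontology <- function(n_terms, max_parents = 2L, seed = 1L,
                                  ids = sprintf("TOY:%04d",
                                                seq_len(n_terms))) {
  stopifnot(n_terms >= 1L, max_parents >= 1L, length(ids) == n_terms)
  set.seed(seed)
  terms <- data.table::data.table(id = ids,
                                  name = sprintf("toy term %d",
                                                 seq_len(n_terms)))
  edges <- list()
  for (i in seq_len(n_terms)[-1]) {
    k <- sample.int(min(max_parents, i - 1L), 1L)
    parents <- sample.int(i - 1L, k)
    edges[[length(edges) + 1L]] <-
      data.table::data.table(child = ids[i], parent = ids[parents])
  }
  edges <- if (length(edges)) data.table::rbindlist(edges) else
    data.table::data.table(child = character(), parent = character())
  ontology_graph(terms, edges)
}

#' The anucleate-cell three-term ontology fixture
#'
#' The classic Cell Ontology neighbourhood used to illustrate the distance
#' score: corneocyte and platelet are both subclasses of anucleate cell, so
#' child-parent distance is 1 and the two siblings are at distance 2.
#'
#' @return An `ontology_graph` with three terms and two is_a edges.
#' @export
anucleate_cell_ontology <- function() {
  ontology_graph(
    data.table::data.table(
      id = c("CL:0000225", "CL:0002153", "CL:0000233"),
      name = c("anucleate cell", "corneocyte", "platelet")),
    data.table::data.table(child = c("CL:0002153", "CL:0000233"),
                           parent = c("CL:0000225", "CL:0000225")))
}

#' Generate a cluster-mean expression matrix with planted markers
#'
#' Baseline expression is uniform noise around `base_mean`; each cluster's
#' planted marker genes are multiplied by `effect` in that cluster only.
#' `effect = 1` makes markers indistinguishable from background (null
#' case).
#'
#' @param n_clusters,n_genes Matrix dimensions
#'   (`markers_per_cluster * n_clusters <= n_genes`).
#' @param markers_per_cluster Planted markers per cluster.
#' @param effect Fold elevation of a marker in its own cluster.
#' @param seed Integer seed.
#' @param base_mean Baseline mean expression.
#' @param gene_names,cluster_names Optional dimension names.
#' @return `list(expr =, markers =, cluster_names =)`; `markers` is a named
#'   list of each cluster's planted genes.
#' @export
generate_expression_matrix <- function(n_clusters, n_genes,
                                       markers_per_cluster, effect = 5,
                                       seed = 1L, base_mean = 1,
                                       gene_names = sprintf("SGENE%d",
                                                            seq_len(n_genes)),
                                       cluster_names = sprintf("cluster%d",
                                                               seq_len(n_clusters))) {
  stopifnot(markers_per_cluster * n_clusters <= n_genes)
  set.seed(seed)
  expr <- matrix(stats::runif(n_clusters * n_genes, 0.5, 1.5) * base_mean,
                 n_clusters, n_genes,
                 dimnames = list(cluster_names, gene_names))
  markers <- list()
  idx <- seq_len(markers_per_cluster)
  for (cl in seq_len(n_clusters)) {
    cols <- (cl - 1L) * markers_per_cluster + idx
    expr[cl, cols] <- expr[cl, cols] * effect
    markers[[cluster_names[cl]]] <- gene_names[cols]
  }
  list(expr = expr, markers = markers, cluster_names = cluster_names)
}

#' Cluster-mean expression matrix aligned with a synthetic truth
#'
#' Clusters are the truth's cell types (named by their ontology term ids);
#' each cluster's planted markers are the genes planted on that cell type.
#'
#' @param truth A [synthetic_truth()].
#' @param effect Fold elevation of planted markers.
#' @return As [generate_expression_matrix()].
#' @export
truth_expression <- function(truth, effect = 5) {
  set.seed(truth$seed + 2L)
  expr <- matrix(stats::runif(truth$n_cells * truth$n_genes, 0.5, 1.5),
                 truth$n_cells, truth$n_genes,
                 dimnames = list(truth$cell_cuis, truth$gene_symbols))
  markers <- list()
  for (cl in seq_len(truth$n_cells)) {
    cols <- which(truth$planted == cl)
    if (length(cols)) expr[cl, cols] <- expr[cl, cols] * effect
    markers[[truth$cell_cuis[cl]]] <- truth$gene_symbols[cols]
  }
  list(expr = expr, markers = markers, cluster_names = truth$cell_cuis)
}

#' Deterministic literature demo: one gene, five blood cell types
#'
#' Builds a small corpus whose aggregated evidence reproduces a realistic
#' published-scale search result for the gene A1BG (alpha-1-B glycoprotein)
#' against five blood cell types, with (distinct articles, total
#' co-occurrences) of (110, 222), (64, 204), (67, 188), (73, 129) and
#' (35, 80). Per cell type the total weight is spread over the articles so
#' every article contributes at least one co-occurrence. Useful as a worked
#' example and as the reference fixture for ranking checks.
#'
#' @return `list(articles =, gene_catalog =, cell_catalog =, expected =)`;
#'   `expected` holds the per-cell counts.
#' @export
demo_corpus <- function() {
  cells <- data.table::data.table(
    cui = c("CL:0000236", "CL:0000233", "CL:0000595", "CL:0000084",
            "CL:0000775"),
    canonical_name = c("B cell", "Platelet", "Enucleate erythrocyte",
                       "T cell", "Neutrophil"),
    abbreviation = "", gene_type = "", synonyms = "")
  counts <- data.table::data.table(
    cell_cui = cells$cui, c_pmid = c(110L, 64L, 67L, 73L, 35L),
    c_total = c(222L, 204L, 188L, 129L, 80L))
  gene <- data.table::data.table(
    cui = "GENE:0001", canonical_name = "alpha-1-B glycoprotein",
    abbreviation = "A1BG", gene_type = "protein-coding", synonyms = "A1B")
  articles <- list()
  pmid <- 500001L
  for (i in seq_len(nrow(counts))) {
    p <- counts$c_pmid[i]; total <- counts$c_total[i]
    w <- c(total - p + 1L, rep(1L, p - 1L))
    for (k in seq_len(p)) {
      tokens <- rep(c("A1BG", cells$canonical_name[i]), each = w[k])
      classes <- rep(c("gene", "cell_type"), each = w[k])
      ids <- rep(c("GENE:0001", counts$cell_cui[i]), each = w[k])
      title <- sprintf("Blood cell study %d", pmid)
      width <- nchar(tokens)
      end <- nchar(title) + 1L + cumsum(width + 1L) - 1L
      articles[[length(articles) + 1L]] <- annotated_article(
        pmid, mention_table(tokens, classes, ids, end - width, end),
        title = title, abstract = paste(tokens, collapse = " "))
      pmid <- pmid + 1L
    }
  }
  list(articles = articles,
       gene_catalog = concept_catalog(gene, "gene"),
       cell_catalog = concept_catalog(cells, "cell_type"),
       expected = counts)
}

#' Write the expression matrix as TSV
#'
#' First column `cluster`, one column per gene.
#'
#' @param expr Cluster x gene matrix.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  dt <- data.table::as.data.table(expr, keep.rownames = "cluster")
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' Write a curated marker database as TSV
#'
#' @param db `data.table` with columns `cell_cui`, `gene`.
#' @param path Output path.
#' @export
write_marker_db <- function(db, path) {
  data.table::fwrite(db[, .(cell_cui, gene)], path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}
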