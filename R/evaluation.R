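#' Select top differentially expressed genes per cluster
#'
#' For each expression cluster, genes are ranked by a one-versus-rest
#' expression ratio: `(mean in cluster + pseudocount) / (mean of the other
#' clusters' means + pseudocount)`, descending, ties broken by gene name
#' ascending, and the top `n` (default 50) are returned as that cluster's
#' marker genes.
#'
#' @param expr Numeric matrix of cluster mean expression, clusters in rows
#'   (rownames) and genes in columns (colnames); values >= 0.
#' @param n Number of genes per cluster (default 50).
#' @param pseudocount Added to numerator and denominator to stabilise
#'   ratios at zero expression (default 1e-9).
#' @return Named list, one ordered character vector of genes per cluster.
#' @export
select_top_degs <- function(expr, n = 50L, pseudocount = 1e-9) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2L) stop("at least two clusters are required")
  if (any(expr < 0)) stop("expression values must be non-negative")
  genes <- colnames(expr)
  if (is.null(genes)) stop("expression matrix must have gene column names")
  if (n > length(genes)) {
    message("n = ", n, " exceeds the ", length(genes),
            " available genes; returning all genes")
    n <- length(genes)
  }
  out <- lapply(rownames(expr), function(cl) {
    others <- colMeans(expr[rownames(expr) != cl, , drop = FALSE])
    ratio <- (expr[cl, ] + pseudocount) / (others + pseudocount)
    ord <- order(-ratio, genes)
    genes[ord][seq_len(n)]
  })
  stats::setNames(out, rownames(expr))
}

#' Marker sources: ranked cell types for a gene
#'
#' A marker source answers "which cell types does this database associate
#' with gene X, best first". Two adapters are provided:
#' `atlas_marker_source()` wraps deployment rows plus catalogues and ranks
#' by relation score via [query_gene()]; `curated_marker_source()` wraps a
#' simple curated marker table (TSV columns `cell_cui`, `gene`), ranking
#' either by file order (default) or by each cell type's marker count —
#' curated databases carry no co-occurrence counts, so rank choice is an
#' explicit interpretation.
#'
#' @param deployment,gene_catalog,cell_catalog See [query_gene()].
#' @param exact Exact term matching for gene lookup.
#' @return An object with class `marker_source` answering [rank_cells()].
#' @export
atlas_marker_source <- function(deployment, gene_catalog, cell_catalog,
                                exact = TRUE) {
  structure(list(deployment = deployment, gene_catalog = gene_catalog,
                 cell_catalog = cell_catalog, exact = exact),
            class = c("atlas_marker_source", "marker_source"))
}

#' @rdname atlas_marker_source
#' @param x TSV path or `data.frame` with columns `cell_cui`, `gene`.
#' @param rank_by Rank rule among a gene's cell types.
#' @export
curated_marker_source <- function(x, rank_by = c("file_order",
                                                 "marker_count")) {
  rank_by <- match.arg(rank_by)
  tab <- if (is.character(x)) {
    data.table::fread(x, sep = "\t", colClasses = "character")
  } else data.table::as.data.table(x)
  stopifnot(all(c("cell_cui", "gene") %in% names(tab)))
  tab[, file_order := .I]
  tab[, gene_folded := tolower(gene)]
  counts <- tab[, .(n_markers = .N), by = cell_cui]
  tab <- counts[tab, on = "cell_cui"]
  structure(list(table = tab, rank_by = rank_by),
            class = c("curated_marker_source", "marker_source"))
}

#' Ranked cell types for one gene
#'
#' @param source A `marker_source`.
#' @param gene Gene query string.
#' @return Character vector of cell-type term ids, best first (empty when
#'   the gene has no hits).
#' @export
rank_cells <- function(source, gene) UseMethod("rank_cells")

#' @export
rank_cells.atlas_marker_source <- function(source, gene) {
  hits <- query_gene(source$deployment, gene, source$gene_catalog,
                     source$cell_catalog, exact = source$exact)
  hits$cui
}

#' @export
rank_cells.curated_marker_source <- function(source, gene) {
  gene_key <- tolower(gene)
  rows <- source$table[gene_folded == gene_key]
  if (nrow(rows) == 0L) return(character())
  rows <- if (source$rank_by == "marker_count") {
    rows[order(-n_markers, cell_cui)]
  } else rows[order(file_order)]
  unique(rows$cell_cui)
}

#' Top-1 hit and its ontology distance to the reference cell type
#'
#' Queries the marker source for the gene, takes the top-ranked cell type,
#' and measures its [term_distance()] to the annotated reference cell type:
#' 0 means identical, 1 a parent/child, 2 a sibling. A gene without any hit
#' is unmatched (`NA` in both fields).
#'
#' @param source A `marker_source`.
#' @param ontology An `ontology_graph` containing the reference term.
#' @param gene Gene query string.
#' @param reference_cell Reference cell-type term id.
#' @return `list(top1 =, distance =)`, each `NA` when unmatched. Hits whose
#'   term is absent from the ontology fall through to the next-ranked hit.
#' @export
top1_distance <- function(source, ontology, gene, reference_cell) {
  if (!reference_cell %in% ontology_ids(ontology)) {
    stop("reference cell type not in ontology: ", reference_cell)
  }
  cells <- rank_cells(source, gene)
  cells <- cells[cells %in% ontology_ids(ontology)]
  if (!length(cells)) {
    return(list(top1 = NA_character_, distance = NA_integer_))
  }
  list(top1 = cells[1],
       distance = term_distance(ontology, cells[1], reference_cell))
}

#' Combined distance over two marker databases
#'
#' The combined per-gene distance is the minimum of the matched top-1-hit
#' distances; when only one database matched the gene, its singular top-1
#' distance is used. Both unmatched is an error (callers filter first) when
#' `strict`, else `NA`.
#'
#' @param d_a,d_b Integer distances, `NA` for unmatched (vectorised).
#' @param strict Error on a pair with both sides unmatched.
#' @return Integer vector of combined distances.
#' @export
combined_distance <- function(d_a, d_b, strict = FALSE) {
  both_na <- is.na(d_a) & is.na(d_b)
  if (strict && any(both_na)) {
    stop("combined distance undefined: unmatched in both databases")
  }
  pmin(d_a, d_b, na.rm = TRUE)
}

#' Categorise genes by database membership
#'
#' Each gene is assigned to exactly one of four categories by whether it has
#' any cell-type hit in database A, database B, both, or neither; the counts
#' always sum to the gene-list length.
#'
#' @param genes Character vector of gene query strings.
#' @param db_a,db_b `marker_source` objects.
#' @return Named integer vector `c(a_only, both, b_only, neither)`.
#' @export
categorize_gene_matches <- function(genes, db_a, db_b) {
  in_a <- vapply(genes, function(g) length(rank_cells(db_a, g)) > 0L,
                 logical(1))
  in_b <- vapply(genes, function(g) length(rank_cells(db_b, g)) > 0L,
                 logical(1))
  c(a_only = sum(in_a & !in_b), both = sum(in_a & in_b),
    b_only = sum(!in_a & in_b), neither = sum(!in_a & !in_b))
}

#' Evaluate marker genes against two databases
#'
#' The benchmark procedure: for every (gene, reference cell type) pair,
#' query both marker sources, record each database's top-1 cell type and
#' its ontology distance to the reference, and the combined (minimum)
#' distance. Unreachable ontology pairs follow `unreachable_policy`:
#' `"exclude"` treats them as unmatched, `"penalize"` replaces them with
#' `penalty`.
#'
#' @param genes Character vector of marker genes.
#' @param reference_cells Reference cell-type term id per gene (recycled if
#'   length 1).
#' @param db_a,db_b `marker_source` objects (atlas and curated database).
#' @param ontology An `ontology_graph`.
#' @param unreachable_policy `"exclude"` or `"penalize"`.
#' @param penalty Distance substituted under `"penalize"`.
#' @return `data.table` of evaluation records: `gene`, `reference_cell`,
#'   `top1_a`, `top1_b`, `dist_a`, `dist_b`, `combined`.
#' @export
evaluate_markers <- function(genes, reference_cells, db_a, db_b, ontology,
                             unreachable_policy = c("exclude", "penalize"),
                             penalty = NA_integer_) {
  unreachable_policy <- match.arg(unreachable_policy)
  reference_cells <- rep_len(reference_cells, length(genes))
  rec <- lapply(seq_along(genes), function(i) {
    a <- top1_distance(db_a, ontology, genes[i], reference_cells[i])
    b <- top1_distance(db_b, ontology, genes[i], reference_cells[i])
    fix <- function(hit) {
      if (!is.na(hit$top1) && is.na(hit$distance)) {
        if (unreachable_policy == "penalize") hit$distance <- penalty
        else hit$top1 <- NA_character_
      }
      hit
    }
    a <- fix(a); b <- fix(b)
    data.table::data.table(
      gene = genes[i], reference_cell = reference_cells[i],
      top1_a = a$top1, top1_b = b$top1,
      dist_a = as.integer(a$distance), dist_b = as.integer(b$distance),
      combined = as.integer(combined_distance(a$distance, b$distance)))
  })
  data.table::rbindlist(rec)
}

#' Per-cell-type summary of evaluation records
#'
#' Summarises records by reference cell type: either the mean per-gene
#' difference `dist_a - dist_b` over genes matched in both databases
#' (`"per_db_difference"`; negative favours database A), or the mean
#' combined distance over genes matched in at least one
#' (`"combined"`). The band is the sample standard deviation (n-1
#' denominator; 0 with a flag when n = 1). Cell types with no usable
#' record are omitted.
#'
#' @param records Output of [evaluate_markers()].
#' @param mode Summary mode.
#' @return `data.table`: `reference_cell`, `mean`, `sigma`, `n`,
#'   `single_record` flag.
#' @export
summarize_by_celltype <- function(records,
                                  mode = c("per_db_difference", "combined")) {
  mode <- match.arg(mode)
  use <- if (mode == "per_db_difference") {
    records[!is.na(dist_a) & !is.na(dist_b),
            .(value = as.numeric(dist_a - dist_b), reference_cell)]
  } else {
    records[!is.na(combined), .(value = as.numeric(combined),
                                reference_cell)]
  }
  if (nrow(use) == 0L) {
    return(data.table::data.table(reference_cell = character(),
                                  mean = numeric(), sigma = numeric(),
                                  n = integer(), single_record = logical()))
  }
  out <- use[, .(mean = mean(value),
                 sigma = if (.N > 1L) stats::sd(value) else 0,
                 n = .N, single_record = .N == 1L),
             by = reference_cell]
  data.table::setorder(out, reference_cell)[]
}

#' Write an evaluation report
#'
#' Emits the per-gene records as TSV and a JSON summary holding the match
#' categories and both per-cell-type summaries.
#'
#' @param records Output of [evaluate_markers()].
#' @param categories Output of [categorize_gene_matches()].
#' @param path_tsv,path_json Output paths (either may be `NULL` to skip).
#' @export
write_eval_report <- function(records, categories, path_tsv = NULL,
                              path_json = NULL) {
  if (!is.null(path_tsv)) {
    data.table::fwrite(records, path_tsv, sep = "\t", quote = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(categories = as.list(categories),
           per_db_difference = summarize_by_celltype(records,
                                                     "per_db_difference"),
           combined = summarize_by_celltype(records, "combined")),
      path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(records)
}
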