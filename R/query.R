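#' Attach relevance scores to deployment rows
#'
#' @param rows Aggregated relation rows.
#' @return Copy of the rows with a `score` column
#'   (`relation_score(c_pmid, c_total)`).
#' @export
score_deployment <- function(rows) {
  out <- data.table::copy(rows)
  out[, score := relation_score(c_pmid, c_total)][]
}

empty_hits <- function(note = NULL) {
  h <- data.table::data.table(
    query_cui = character(), cui = character(), name = character(),
    c_pmid = integer(), c_total = integer(), score = numeric(),
    pmids = list())
  if (!is.null(note)) data.table::setattr(h, "resolution_note", note)
  h
}

rank_hits <- function(hits) {
  data.table::setorder(hits, -score, -c_pmid, name)[]
}

query_counterparts <- function(deployment, resolved, query_side,
                               counter_catalog, score_cutoff, limit,
                               gene_type_filter = NULL) {
  query_col <- if (query_side == "gene") "gene_cui" else "cell_cui"
  counter_col <- if (query_side == "gene") "cell_cui" else "gene_cui"
  rows <- deployment[deployment[[query_col]] %in% resolved$cui]
  if (nrow(rows) == 0L) return(empty_hits("term resolved but no relations"))
  hits <- data.table::data.table(
    query_cui = rows[[query_col]], cui = rows[[counter_col]],
    c_pmid = rows$c_pmid, c_total = rows$c_total,
    pmids = if ("pmids" %in% names(rows)) rows$pmids
            else rep(list(integer()), nrow(rows)))
  rec <- catalog_record(counter_catalog, hits$cui)
  hits[, name := rec$canonical_name]
  hits[is.na(name), name := cui]
  if (!is.null(gene_type_filter)) {
    keep <- !is.na(rec$gene_type) & rec$gene_type == gene_type_filter
    hits <- hits[keep]
  }
  if (nrow(hits) == 0L) return(empty_hits("all counterparts filtered out"))
  hits[, score := relation_score(c_pmid, c_total)]
  hits <- hits[score >= score_cutoff]
  rank_hits(hits)
  if (is.finite(limit)) hits <- utils::head(hits, limit)
  data.table::setcolorder(hits, c("query_cui", "cui", "name", "c_pmid",
                                  "c_total", "score", "pmids"))[]
}

#' Query the atlas for a gene and rank its cell-type relations
#'
#' Resolves the free-text term against the gene catalogue (see
#' [resolve_query_term()]), collects the cell-type counterparts of every
#' resolved gene concept from the deployment rows, scores each relation
#' with [relation_score()], and returns them sorted by score descending
#' (ties: `c_pmid` descending, then counterpart name ascending). An
#' unresolvable term yields an empty result carrying a `resolution_note`
#' attribute, not an error.
#'
#' @param deployment Aggregated (typically filtered) relation rows.
#' @param term Query string.
#' @param gene_catalog,cell_catalog Concept catalogues.
#' @param exact Exact-match flag for term resolution.
#' @param score_cutoff Drop hits scoring below this value.
#' @param limit Maximum number of hits returned.
#' @return `data.table` of hits: `query_cui`, counterpart `cui`, `name`,
#'   `c_pmid`, `c_total`, `score`, `pmids`.
#' @export
query_gene <- function(deployment, term, gene_catalog, cell_catalog,
                       exact = TRUE, score_cutoff = -Inf, limit = Inf) {
  resolved <- resolve_query_term(term, gene_catalog, exact = exact)
  if (nrow(resolved) == 0L) {
    return(empty_hits(paste0("unresolved gene term: ", term)))
  }
  query_counterparts(deployment, resolved, "gene", cell_catalog,
                     score_cutoff, limit)
}

#' Query the atlas for a cell type and rank its gene relations
#'
#' Mirror of [query_gene()] with gene counterparts; `gene_type_filter`
#' restricts the hits to genes of one catalogued type (e.g.
#' `"protein-coding"`).
#'
#' @inheritParams query_gene
#' @param gene_type_filter Optional gene-type restriction on the hits.
#' @export
query_cell <- function(deployment, term, gene_catalog, cell_catalog,
                       exact = TRUE, gene_type_filter = NULL,
                       score_cutoff = -Inf, limit = Inf) {
  resolved <- resolve_query_term(term, cell_catalog, exact = exact)
  if (nrow(resolved) == 0L) {
    return(empty_hits(paste0("unresolved cell term: ", term)))
  }
  query_counterparts(deployment, resolved, "cell", gene_catalog,
                     score_cutoff, limit, gene_type_filter)
}

#' Annotate a marker-gene list with ranked cell types
#'
#' Queries every gene of the list and combines the per-gene relation scores
#' per candidate cell type: `"sum"` (default; rewards both breadth and
#' strength), `"mean"` over the matched genes, or `"count"` of matched
#' genes. Cell types are ranked by combined score descending with the same
#' tie rules as [query_gene()]. The per-gene contribution table is attached
#' as attribute `"contributions"`; unresolved genes are listed in attribute
#' `"resolution_notes"`.
#'
#' @inheritParams query_gene
#' @param genes Non-empty character vector of gene query terms.
#' @param combine Combination rule.
#' @return `data.table`: `cui`, `name`, `combined_score`, `n_genes`.
#' @export
annotate_marker_list <- function(deployment, genes, gene_catalog,
                                 cell_catalog,
                                 combine = c("sum", "mean", "count"),
                                 exact = TRUE, score_cutoff = -Inf) {
  combine <- match.arg(combine)
  if (!length(genes)) stop("gene list must be non-empty")
  notes <- character()
  contrib <- list()
  for (g in genes) {
    hits <- query_gene(deployment, g, gene_catalog, cell_catalog,
                       exact = exact, score_cutoff = score_cutoff)
    if (nrow(hits) == 0L) {
      notes <- c(notes, attr(hits, "resolution_note") %||%
                   paste0("no hits: ", g))
      next
    }
    contrib[[length(contrib) + 1L]] <-
      data.table::data.table(gene = g, cui = hits$cui, name = hits$name,
                             score = hits$score)
  }
  if (!length(contrib)) {
    out <- data.table::data.table(cui = character(), name = character(),
                                  combined_score = numeric(),
                                  n_genes = integer())
    data.table::setattr(out, "resolution_notes", notes)
    return(out)
  }
  contrib <- data.table::rbindlist(contrib)
  out <- contrib[, .(combined_score = switch(combine,
                                             sum = sum(score),
                                             mean = mean(score),
                                             count = as.numeric(.N)),
                     n_genes = data.table::uniqueN(gene)),
                 by = .(cui, name)]
  data.table::setorder(out, -combined_score, name)
  data.table::setattr(out, "contributions", contrib)
  data.table::setattr(out, "resolution_notes", notes)
  out[]
}

#' Build a co-occurrence graph for a set of query terms
#'
#' Runs [query_gene()]/[query_cell()] for every term (against both
#' catalogues), merges the per-term result subgraphs, and returns an igraph
#' object: concept nodes carry `class` (gene/cell_type), a display `label`
#' (gene abbreviation when available), the `full_name`, and a
#' `size_weight`; edges carry the relation score as `weight`. The node
#' weight summarises incident edge scores (`"max"` by default, `"sum"`
#' selectable). Gene-gene edges are not generated: the evidence schema is
#' gene x cell-type.
#'
#' @inheritParams query_gene
#' @param terms Character vector of query terms (genes and/or cell types).
#' @param node_weight Node weight rule over incident edge scores.
#' @return An `igraph` object (possibly empty when nothing resolves).
#' @export
build_cooccurrence_graph <- function(deployment, terms, gene_catalog,
                                     cell_catalog, exact = TRUE,
                                     score_cutoff = -Inf, limit = Inf,
                                     node_weight = c("max", "sum")) {
  node_weight <- match.arg(node_weight)
  edges <- list()
  for (term in terms) {
    gh <- query_gene(deployment, term, gene_catalog, cell_catalog,
                     exact = exact, score_cutoff = score_cutoff,
                     limit = limit)
    if (nrow(gh)) {
      edges[[length(edges) + 1L]] <-
        data.table::data.table(gene_cui = gh$query_cui, cell_cui = gh$cui,
                               weight = gh$score)
    }
    ch <- query_cell(deployment, term, gene_catalog, cell_catalog,
                     exact = exact, score_cutoff = score_cutoff,
                     limit = limit)
    if (nrow(ch)) {
      edges[[length(edges) + 1L]] <-
        data.table::data.table(gene_cui = ch$cui, cell_cui = ch$query_cui,
                               weight = ch$score)
    }
  }
  if (!length(edges)) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  edges <- unique(data.table::rbindlist(edges))
  gene_rec <- catalog_record(gene_catalog, unique(edges$gene_cui))
  cell_rec <- catalog_record(cell_catalog, unique(edges$cell_cui))
  nodes <- data.table::rbindlist(list(
    data.table::data.table(
      name = gene_rec$cui, class = "gene",
      label = ifelse(is.na(gene_rec$abbreviation) |
                       !nzchar(gene_rec$abbreviation),
                     gene_rec$canonical_name, gene_rec$abbreviation),
      full_name = gene_rec$canonical_name),
    data.table::data.table(
      name = cell_rec$cui, class = "cell_type",
      label = cell_rec$canonical_name,
      full_name = cell_rec$canonical_name)))
  nodes[is.na(label), label := name]
  nodes[is.na(full_name), full_name := name]
  incident <- data.table::rbindlist(list(
    edges[, .(name = gene_cui, weight)], edges[, .(name = cell_cui, weight)]))
  nw <- incident[, .(size_weight = if (node_weight == "max") max(weight)
                                   else sum(weight)), by = name]
  nodes <- nw[nodes, on = "name"]
  igraph::graph_from_data_frame(
    edges[, .(from = gene_cui, to = cell_cui, weight)],
    directed = FALSE,
    vertices = nodes[, .(name, class, label, full_name, size_weight)])
}

#' Export / import a co-occurrence graph
#'
#' Lossless serialisation of nodes, edges, weights and labels as GraphML or
#' node-link JSON (`{"nodes": [...], "links": [...]}`, loadable by common
#' graph viewers). Layout and rendering are left to the consumer.
#'
#' @param graph An `igraph` co-occurrence graph.
#' @param path Output file path.
#' @param format `"graphml"` or `"node-link-json"`.
#' @export
export_graph <- function(graph, path,
                         format = c("graphml", "node-link-json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    nodes <- data.frame(id = igraph::V(graph)$name %||% character(),
                        stringsAsFactors = FALSE)
    for (at in igraph::vertex_attr_names(graph)) {
      if (at != "name") nodes[[at]] <- igraph::vertex_attr(graph, at)
    }
    links <- data.frame(source = el[, 1], target = el[, 2],
                        stringsAsFactors = FALSE)
    for (at in igraph::edge_attr_names(graph)) {
      links[[at]] <- igraph::edge_attr(graph, at)
    }
    jsonlite::write_json(list(directed = FALSE, nodes = nodes,
                              links = links),
                         path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = c("graphml", "node-link-json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- data.table::as.data.table(obj$nodes)
  links <- data.table::as.data.table(obj$links)
  if (nrow(nodes) == 0L) return(igraph::make_empty_graph(directed = FALSE))
  data.table::setnames(nodes, "id", "name")
  if (nrow(links)) {
    data.table::setnames(links, c("source", "target"), c("from", "to"))
  } else {
    links <- data.table::data.table(from = character(), to = character())
  }
  igraph::graph_from_data_frame(links, directed = FALSE, vertices = nodes)
}

#' Export ranked query hits as a delimited table
#'
#' Columns match the published result-table layout: counterpart name,
#' distinct supporting articles, total co-occurrences, the score displayed
#' at 2 decimals, and the supporting pmids semicolon-separated.
#'
#' @param hits Result of [query_gene()]/[query_cell()].
#' @param path Output path.
#' @param sep Field separator (tab default; use `","` for CSV).
#' @export
export_hits <- function(hits, path, sep = "\t") {
  out <- data.table::data.table(
    name = hits$name, c_pmid = hits$c_pmid, c_total = hits$c_total,
    score = sprintf("%.2f", format_score(hits$score)),
    pmids = vapply(hits$pmids, paste, character(1), collapse = ";"))
  data.table::fwrite(out, path, sep = sep, quote = FALSE)
  invisible(path)
}
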