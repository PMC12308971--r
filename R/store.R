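#' Create or open an atlas evidence store
#'
#' The production store keeps one evidence row per
#' `(gene_cui, cell_cui, pmid)` plus a log of processed article ids, so that
#' re-ingestion is idempotent and a historical track of articles is kept.
#' It is backed by a schema-versioned directory of TSV tables; pass
#' `path = NULL` for a purely in-memory store.
#'
#' @param path Directory to open (created on [save_store()]), or `NULL`.
#' @return Object of class `atlas_store` (an environment).
#' @export
atlas_store <- function(path = NULL) {
  store <- new.env(parent = emptyenv())
  store$evidence <- empty_evidence()
  store$processed <- integer()
  store$meta <- list(schema_version = 1L)
  store$path <- path
  class(store) <- "atlas_store"
  if (!is.null(path) && file.exists(file.path(path, "evidence.tsv"))) {
    store$evidence <- data.table::fread(
      file.path(path, "evidence.tsv"), sep = "\t",
      colClasses = list(character = c("gene_cui", "cell_cui"),
                        integer = c("pmid", "pair_count")))
    store$processed <- data.table::fread(
      file.path(path, "processed.tsv"), sep = "\t")$pmid
    store$meta <- jsonlite::read_json(file.path(path, "meta.json"),
                                      simplifyVector = TRUE)
  }
  store
}

empty_evidence <- function() {
  data.table::data.table(gene_cui = character(), cell_cui = character(),
                         pmid = integer(), pair_count = integer())
}

#' @export
print.atlas_store <- function(x, ...) {
  cat(sprintf("<atlas_store evidence rows=%d processed articles=%d>\n",
              nrow(x$evidence), length(x$processed)))
  invisible(x)
}

#' Persist a store to its backing directory
#'
#' @param store An `atlas_store`.
#' @param path Directory; defaults to the path the store was opened with.
#' @export
save_store <- function(store, path = store$path) {
  if (is.null(path)) stop("store has no backing path")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(store$evidence, file.path(path, "evidence.tsv"),
                     sep = "\t")
  data.table::fwrite(data.table::data.table(pmid = store$processed),
                     file.path(path, "processed.tsv"), sep = "\t")
  jsonlite::write_json(store$meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE)
  store$path <- path
  invisible(store)
}

#' Per-article gene x cell-type co-occurrence evidence
#'
#' Every distinct pair of a mapped gene concept and a mapped cell-type
#' concept mentioned in the same article contributes one evidence row. The
#' per-article weight is pluggable: `"min"` (default) takes the smaller of
#' the two concepts' mention counts, bounding inflation from one
#' hyper-mentioned entity; `"product"` counts all mention pairs; `"binary"`
#' contributes 1 per article.
#'
#' @param article An `annotated_article` whose mentions are already filtered
#'   to mapped gene/cell mentions (see [filter_mapped_mentions()]).
#' @param strategy Co-occurrence counting strategy.
#' @return `data.table` with columns `gene_cui`, `cell_cui`, `pmid`,
#'   `pair_count`; empty when either entity class is absent.
#' @export
compute_article_cooccurrences <- function(article,
                                          strategy = c("min", "product",
                                                       "binary")) {
  strategy <- match.arg(strategy)
  m <- article$mentions[!is.na(concept_id)]
  genes <- m[entity_class == "gene", .(g_n = .N), by = .(gene_cui = concept_id)]
  cells <- m[entity_class == "cell_type",
             .(c_n = .N), by = .(cell_cui = concept_id)]
  if (nrow(genes) == 0L || nrow(cells) == 0L) return(empty_evidence())
  pairs <- data.table::CJ(gene_cui = genes$gene_cui, cell_cui = cells$cell_cui)
  pairs <- genes[pairs, on = "gene_cui"]
  pairs <- cells[pairs, on = "cell_cui"]
  pairs[, pair_count := switch(strategy,
                               min = pmin(g_n, c_n),
                               product = g_n * c_n,
                               binary = 1L)]
  pairs[, `:=`(pmid = article$pmid, g_n = NULL, c_n = NULL)]
  data.table::setcolorder(pairs, c("gene_cui", "cell_cui", "pmid",
                                   "pair_count"))
  data.table::setorder(pairs, gene_cui, cell_cui)[]
}

#' Ingest annotated articles into the production store
#'
#' Articles whose pmid is already in the processed-article log are skipped
#' entirely, making re-ingestion idempotent; duplicate pmids within the
#' batch keep the first occurrence. The batch is committed atomically: on
#' any failure the store is left unchanged.
#'
#' @param store An `atlas_store`.
#' @param articles List of filtered `annotated_article` objects.
#' @inheritParams compute_article_cooccurrences
#' @return Ingestion report: `list(inserted =, skipped =)` article counts.
#' @export
ingest_articles <- function(store, articles,
                            strategy = c("min", "product", "binary")) {
  strategy <- match.arg(strategy)
  new_rows <- list()
  new_pmids <- integer()
  inserted <- 0L; skipped <- 0L
  seen <- store$processed
  for (art in articles) {
    if (art$pmid %in% seen) { skipped <- skipped + 1L; next }
    seen <- c(seen, art$pmid)
    new_pmids <- c(new_pmids, art$pmid)
    ev <- compute_article_cooccurrences(art, strategy)
    if (nrow(ev)) new_rows[[length(new_rows) + 1L]] <- ev
    inserted <- inserted + 1L
  }
  # commit only after the whole batch computed cleanly
  store$evidence <- data.table::rbindlist(c(list(store$evidence), new_rows))
  store$processed <- c(store$processed, new_pmids)
  list(inserted = inserted, skipped = skipped)
}

#' Aggregate the production store into deployment rows
#'
#' Groups evidence by `(gene_cui, cell_cui)` and computes `c_pmid` (distinct
#' supporting articles) and `c_total` (summed per-article co-occurrence
#' weight), plus the supporting pmids for traceability. Rows are ordered by
#' `gene_cui`, `cell_cui` ascending, so the operation is deterministic and
#' invariant to article order.
#'
#' @param store An `atlas_store`.
#' @param keep_pmids Keep a `pmids` list-column of supporting article ids.
#' @return `data.table` with columns `gene_cui`, `cell_cui`, `c_pmid`,
#'   `c_total` (and `pmids`).
#' @export
aggregate_to_deployment <- function(store, keep_pmids = TRUE) {
  ev <- store$evidence
  agg <- ev[, .(c_pmid = data.table::uniqueN(pmid),
                c_total = sum(pair_count),
                pmids = list(sort(unique(pmid)))),
            by = .(gene_cui, cell_cui)]
  if (!keep_pmids) agg[, pmids := NULL]
  data.table::setorder(agg, gene_cui, cell_cui)[]
}

#' Apply the deployment filter
#'
#' Retains relations supported by at least `min_pmids` distinct articles
#' (default 3, the published deployment threshold) and at least `min_total`
#' total co-occurrences; order is preserved.
#'
#' @param rows Aggregated relation rows.
#' @param min_pmids,min_total Integer thresholds, both >= 1.
#' @return The surviving rows.
#' @export
apply_deployment_filter <- function(rows, min_pmids = 3L, min_total = 1L) {
  stopifnot(min_pmids >= 1L, min_total >= 1L)
  rows[c_pmid >= min_pmids & c_total >= min_total]
}

#' Merge incrementally aggregated deployment rows
#'
#' Adds per-pair counts from two aggregations over disjoint article sets;
#' pairs unique to either side pass through. When both sides carry `pmids`
#' provenance, overlapping article sets are refused.
#'
#' @param base,delta Aggregated relation rows.
#' @return Merged rows, ordered by `gene_cui`, `cell_cui`.
#' @export
merge_incremental <- function(base, delta) {
  has_prov <- "pmids" %in% names(base) && "pmids" %in% names(delta)
  if (has_prov &&
      length(intersect(unlist(base$pmids), unlist(delta$pmids)))) {
    stop("merge refused: base and delta share article provenance")
  }
  both <- data.table::rbindlist(list(base, delta), fill = TRUE)
  out <- if (has_prov) {
    both[, .(c_pmid = sum(c_pmid), c_total = sum(c_total),
             pmids = list(sort(unique(unlist(pmids))))),
         by = .(gene_cui, cell_cui)]
  } else {
    both[, .(c_pmid = sum(c_pmid), c_total = sum(c_total)),
         by = .(gene_cui, cell_cui)]
  }
  data.table::setorder(out, gene_cui, cell_cui)[]
}

#' Export / read deployment rows as TSV
#'
#' Interchange format: tab-separated `gene_cui, cell_cui, c_pmid, c_total`,
#' with supporting pmids (when present) semicolon-separated in a fifth
#' column.
#'
#' @param rows Aggregated relation rows.
#' @param path TSV path.
#' @export
export_deployment <- function(rows, path) {
  out <- data.table::copy(rows)
  if ("pmids" %in% names(out)) {
    out[, pmids := vapply(pmids, paste, character(1), collapse = ";")]
  }
  if ("score" %in% names(out)) out[, score := NULL]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname export_deployment
#' @export
read_deployment <- function(path) {
  rows <- data.table::fread(path, sep = "\t",
                            colClasses = list(character = c("gene_cui",
                                                            "cell_cui")))
  if ("pmids" %in% names(rows)) {
    rows[, pmids := lapply(strsplit(as.character(pmids), ";", fixed = TRUE),
                           as.integer)]
  }
  rows[]
}
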