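#' Create an entity-mention table
#'
#' Mentions are stored as a `data.table` with one row per mention. Offsets
#' are 0-based half-open character positions over the article's title and
#' abstract concatenated with a single newline.
#'
#' @param surface_text Character vector of mention surface strings.
#' @param entity_class Character vector; each element one of `"gene"`,
#'   `"cell_type"` or `"other"`.
#' @param concept_id Normalised concept identifier emitted by the annotator;
#'   `NA` when the annotator produced none.
#' @param span_start,span_end Integer character offsets, `span_start < span_end`.
#' @return A `data.table` with columns `surface_text`, `entity_class`,
#'   `concept_id`, `span_start`, `span_end`.
#' @export
mention_table <- function(surface_text = character(),
                          entity_class = character(),
                          concept_id = character(),
                          span_start = integer(),
                          span_end = integer()) {
  m <- data.table::data.table(
    surface_text = as.character(surface_text),
    entity_class = as.character(entity_class),
    concept_id   = as.character(concept_id),
    span_start   = as.integer(span_start),
    span_end     = as.integer(span_end)
  )
  validate_mentions(m)
  m
}

entity_classes <- c("gene", "cell_type", "other")

validate_mentions <- function(m) {
  if (nrow(m) == 0L) return(invisible(m))
  bad <- !m$entity_class %in% entity_classes
  if (any(bad)) {
    stop("invalid entity_class value(s): ",
         paste(unique(m$entity_class[bad]), collapse = ", "))
  }
  if (any(!is.na(m$span_start) & !is.na(m$span_end) &
          m$span_start >= m$span_end)) {
    stop("mention spans must satisfy span_start < span_end")
  }
  invisible(m)
}

#' Construct an annotated article
#'
#' One article's identifier, optional metadata, title/abstract text and its
#' ordered list of entity mentions.
#'
#' @param pmid Positive integer article identifier.
#' @param mentions A mention table (see [mention_table()]); may be empty.
#' @param title,abstract Article text; used by the writers and for offset
#'   checks, may be empty strings.
#' @param journal,pub_date Optional metadata (`pub_date` as ISO-8601 string).
#' @return An object of class `annotated_article`.
#' @export
annotated_article <- function(pmid, mentions = mention_table(),
                              title = "", abstract = "",
                              journal = NA_character_,
                              pub_date = NA_character_) {
  pmid <- suppressWarnings(as.integer(pmid))
  if (is.na(pmid) || pmid <= 0L) stop("pmid must be a positive integer")
  validate_mentions(mentions)
  structure(
    list(pmid = pmid, title = title, abstract = abstract,
         journal = journal, pub_date = pub_date,
         mentions = data.table::as.data.table(mentions)),
    class = "annotated_article"
  )
}

#' @export
print.annotated_article <- function(x, ...) {
  cat(sprintf("<annotated_article pmid=%d mentions=%d>\n",
              x$pmid, nrow(x$mentions)))
  invisible(x)
}

article_text <- function(article) {
  paste(article$title, article$abstract, sep = "\n")
}

#' Keep only mentions that normalise to catalogued concepts
#'
#' Drops every mention whose `concept_id` is not a member of the identifier
#' set matching its entity class; `other`-class mentions are always dropped.
#' The input article is not modified and mention order is preserved. The
#' operation is idempotent.
#'
#' @param article An `annotated_article`.
#' @param gene_ids,cell_ids Character vectors of catalogue concept ids.
#' @return A new `annotated_article` containing the surviving mentions.
#' @export
filter_mapped_mentions <- function(article, gene_ids, cell_ids) {
  m <- article$mentions
  keep <- !is.na(m$concept_id) &
    ((m$entity_class == "gene" & m$concept_id %in% gene_ids) |
       (m$entity_class == "cell_type" & m$concept_id %in% cell_ids))
  out <- article
  out$mentions <- m[keep]
  out
}
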