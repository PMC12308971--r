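#' Build a concept catalogue
#'
#' A catalogue maps opaque concept unique identifiers (CUIs) to standardised
#' gene or cell-type records and supports case-insensitive name lookup over
#' canonical names, abbreviations and synonyms. It is the offline surrogate
#' for live gene-registry / ontology-lookup services.
#'
#' @param records `data.frame` with columns `cui`, `canonical_name`,
#'   `abbreviation`, `gene_type` (genes only; blank for cells) and
#'   `synonyms` (pipe-separated string).
#' @param concept_class `"gene"` or `"cell_type"`.
#' @return Object of class `concept_catalog` with a `records` table keyed by
#'   cui and a case-folded `name_index` (name -> cui, possibly many-to-many).
#' @export
concept_catalog <- function(records, concept_class = c("gene", "cell_type")) {
  concept_class <- match.arg(concept_class)
  rec <- data.table::as.data.table(records)
  required <- c("cui", "canonical_name")
  missing_col <- setdiff(required, names(rec))
  if (length(missing_col)) {
    stop("catalog is missing required column(s): ",
         paste(missing_col, collapse = ", "))
  }
  for (col in c("abbreviation", "gene_type", "synonyms")) {
    if (!col %in% names(rec)) rec[[col]] <- NA_character_
  }
  dup <- rec$cui[duplicated(rec$cui)]
  if (length(dup)) stop("duplicate cui in catalog: ", dup[1])
  if (any(!nzchar(rec$cui) | is.na(rec$cui))) stop("empty cui in catalog")
  if (any(!nzchar(rec$canonical_name) | is.na(rec$canonical_name))) {
    stop("empty canonical_name in catalog")
  }

  idx <- rec[, {
    syn <- if (is.na(synonyms) || !nzchar(synonyms)) character()
           else strsplit(synonyms, "|", fixed = TRUE)[[1]]
    abbr <- if (!is.na(abbreviation) && nzchar(abbreviation)) abbreviation
            else character()
    nm <- unique(tolower(c(canonical_name, abbr, syn)))
    list(name = nm[nzchar(nm)])
  }, by = cui]
  data.table::setkey(idx, name)
  structure(list(concept_class = concept_class,
                 records = data.table::setkey(rec, cui),
                 name_index = idx),
            class = "concept_catalog")
}

#' @export
print.concept_catalog <- function(x, ...) {
  cat(sprintf("<concept_catalog class=%s records=%d indexed names=%d>\n",
              x$concept_class, nrow(x$records),
              length(unique(x$name_index$name))))
  invisible(x)
}

#' Load a concept catalogue from TSV
#'
#' Expected columns (header row required): `cui`, `canonical_name`,
#' `abbreviation`, `gene_type`, `synonyms` (pipe-separated). Cell-type
#' catalogues leave the gene-only columns blank.
#'
#' @param path TSV file (UTF-8, plain or gzip).
#' @param concept_class `"gene"` or `"cell_type"`.
#' @return A `concept_catalog`.
#' @export
load_catalog <- function(path, concept_class = c("gene", "cell_type")) {
  rec <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL)
  concept_catalog(rec, match.arg(concept_class))
}

#' Write a concept catalogue as TSV
#'
#' @param catalog A `concept_catalog` (or a bare records table).
#' @param path Output path.
#' @export
write_catalog <- function(catalog, path) {
  rec <- if (inherits(catalog, "concept_catalog")) catalog$records
         else data.table::as.data.table(catalog)
  cols <- c("cui", "canonical_name", "abbreviation", "gene_type", "synonyms")
  out <- data.table::copy(rec)[, intersect(cols, names(rec)), with = FALSE]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' All concept ids of a catalogue
#' @param catalog A `concept_catalog`.
#' @return Character vector of cuis.
#' @export
catalog_ids <- function(catalog) catalog$records$cui

catalog_record <- function(catalog, cuis) {
  catalog$records[data.table::data.table(cui = cuis), on = "cui"]
}

#' Unmapped-mention marker
#'
#' Returned by [normalize_mention()] when a mention cannot be resolved to a
#' catalogue concept. Ambiguous surface matches are deliberately not
#' resolved; the annotator's normalised id is the primary key and free-text
#' fallback refuses to guess.
#'
#' @param ambiguous Logical; `TRUE` when the surface text matched more than
#'   one concept.
#' @return Object of class `unmapped_marker`.
#' @export
unmapped_marker <- function(ambiguous = FALSE) {
  structure(list(ambiguous = ambiguous), class = "unmapped_marker")
}

#' Test for the unmapped marker
#' @param x Object to test.
#' @export
is_unmapped <- function(x) inherits(x, "unmapped_marker")

#' Normalise one mention against a catalogue
#'
#' Resolution order: (1) the mention's `concept_id`, if it is a catalogue
#' cui; (2) a case-insensitive exact match of the surface text against the
#' name index, accepted only when unambiguous. Anything else returns the
#' unmapped marker (with `ambiguous = TRUE` for index collisions).
#'
#' @param mention One-row mention table (or a list with the same fields).
#' @param catalog A `concept_catalog` whose class matches the mention's.
#' @return A one-row concept record, or an [unmapped_marker()].
#' @export
normalize_mention <- function(mention, catalog) {
  cls <- mention$entity_class[1]
  if (!identical(cls, catalog$concept_class)) {
    stop("entity class '", cls, "' does not match catalog class '",
         catalog$concept_class, "'")
  }
  id <- mention$concept_id[1]
  if (!is.na(id) && id %in% catalog$records$cui) {
    return(catalog_record(catalog, id))
  }
  hits <- catalog$name_index[.(tolower(mention$surface_text[1])),
                             nomatch = NULL]
  cuis <- unique(hits$cui)
  if (length(cuis) == 1L) return(catalog_record(catalog, cuis))
  unmapped_marker(ambiguous = length(cuis) > 1L)
}

#' Resolve a free-text query term to concept records
#'
#' Exact mode matches the term case-insensitively against canonical names,
#' abbreviations and synonyms; substring mode keeps every record where the
#' term occurs case-insensitively inside any indexed name. Results are
#' sorted by canonical name.
#'
#' @param term Non-empty query string.
#' @param catalog A `concept_catalog`.
#' @param exact Logical flag (default `TRUE`).
#' @return Concept records table (possibly empty), sorted by
#'   `canonical_name` ascending.
#' @export
resolve_query_term <- function(term, catalog, exact = TRUE) {
  if (is.null(term) || is.na(term) || !nzchar(term)) {
    stop("query term must be non-empty")
  }
  key <- tolower(term)
  cuis <- if (exact) {
    catalog$name_index[.(key), nomatch = NULL]$cui
  } else {
    catalog$name_index[grepl(key, name, fixed = TRUE)]$cui
  }
  rec <- catalog_record(catalog, unique(cuis))
  rec[order(canonical_name)]
}
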