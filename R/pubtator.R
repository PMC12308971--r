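#' Default annotation-type to entity-class map
#'
#' Maps an annotator's (case-folded) type strings onto the three entity
#' classes. Unlisted types fall through to `"other"` and are removed by
#' catalogue filtering; in particular cell lines are not cell types.
#'
#' @return Named character vector: annotation type -> entity class.
#' @export
default_type_map <- function() {
  c(gene = "gene", cell_type = "cell_type", cell = "cell_type",
    cell_line = "other")
}

open_text_source <- function(x) {
  if (inherits(x, "connection")) return(list(con = x, close = FALSE))
  if (grepl("\\.gz$", x)) return(list(con = gzfile(x, "rt"), close = TRUE))
  list(con = file(x, "rt"), close = TRUE)
}

read_source_lines <- function(x) {
  src <- open_text_source(x)
  on.exit(if (src$close) close(src$con))
  readLines(src$con, warn = FALSE)
}

map_entity_class <- function(type, type_map) {
  cls <- unname(type_map[tolower(type)])
  cls[is.na(cls)] <- "other"
  cls
}

#' Read articles in PubTator format
#'
#' Parses the standard PubTator interchange dialect: per document a
#' `PMID|t|title` line, a `PMID|a|abstract` line, then tab-separated
#' annotation lines (`pmid, start, end, text, type, id`), with a blank line
#' between documents.
#'
#' Malformed annotation lines are skipped with a warning naming the line
#' number; a block with no `|t|` header is skipped entirely; a duplicate
#' PMID keeps the first block and warns.
#'
#' @param path File path (plain or gzip) or open connection.
#' @param type_map Annotation-type map, see [default_type_map()].
#' @return List of [annotated_article()] objects.
#' @export
read_pubtator <- function(path, type_map = default_type_map()) {
  lines <- read_source_lines(path)
  blocks <- split_blocks(lines)
  articles <- list()
  seen <- integer()
  for (b in blocks) {
    art <- parse_pubtator_block(lines[b$idx], b$idx, type_map)
    if (is.null(art)) next
    if (art$pmid %in% seen) {
      warning("duplicate PMID ", art$pmid, ": keeping first occurrence")
      next
    }
    seen <- c(seen, art$pmid)
    articles[[length(articles) + 1L]] <- art
  }
  articles
}

split_blocks <- function(lines) {
  nonblank <- nzchar(trimws(lines))
  if (!any(nonblank)) return(list())
  grp <- cumsum(c(TRUE, diff(nonblank) == 1L))
  idx <- seq_along(lines)[nonblank]
  unname(lapply(split(idx, grp[nonblank]), function(i) list(idx = i)))
}

parse_pubtator_block <- function(block, line_nos, type_map) {
  title <- NULL; abstract <- ""
  pmid <- NA_integer_
  ann <- list()
  for (k in seq_along(block)) {
    line <- block[k]
    if (grepl("^[0-9]+\\|t\\|", line)) {
      pmid <- as.integer(sub("\\|.*$", "", line))
      title <- sub("^[0-9]+\\|t\\|", "", line)
    } else if (grepl("^[0-9]+\\|a\\|", line)) {
      abstract <- sub("^[0-9]+\\|a\\|", "", line)
    } else {
      f <- strsplit(line, "\t", fixed = TRUE)[[1]]
      start <- suppressWarnings(as.integer(f[2]))
      end <- suppressWarnings(as.integer(f[3]))
      if (length(f) < 5L || is.na(start) || is.na(end) || start >= end) {
        warning("malformed annotation at line ", line_nos[k], ": skipped")
        next
      }
      id <- if (length(f) >= 6L && nzchar(f[6]) && f[6] != "-")
        f[6] else NA_character_
      ann[[length(ann) + 1L]] <- list(
        surface_text = f[4], type = f[5], concept_id = id,
        span_start = start, span_end = end)
    }
  }
  if (is.null(title)) {
    warning("document block without title header near line ",
            line_nos[1], ": skipped")
    return(NULL)
  }
  mentions <- if (length(ann)) {
    a <- data.table::rbindlist(ann)
    mention_table(a$surface_text, map_entity_class(a$type, type_map),
                  a$concept_id, a$span_start, a$span_end)
  } else mention_table()
  annotated_article(pmid, mentions, title = title, abstract = abstract)
}

#' Write articles in PubTator format
#'
#' Inverse of [read_pubtator()]: parse -> write -> parse is the identity on
#' pmids, text and mention sets. `entity_class` is written as the annotation
#' type so the default type map round-trips it.
#'
#' @param articles List of `annotated_article` objects.
#' @param path Output file path (`.gz` for compressed output).
#' @export
write_pubtator <- function(articles, path) {
  out <- character()
  for (art in articles) {
    out <- c(out,
             sprintf("%d|t|%s", art$pmid, art$title),
             sprintf("%d|a|%s", art$pmid, art$abstract))
    m <- art$mentions
    if (nrow(m)) {
      id <- ifelse(is.na(m$concept_id), "-", m$concept_id)
      out <- c(out, sprintf("%d\t%d\t%d\t%s\t%s\t%s", art$pmid,
                            m$span_start, m$span_end, m$surface_text,
                            m$entity_class, id))
    }
    out <- c(out, "")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read line-delimited annotation records
#'
#' Each line is one JSON object describing one article:
#' `{"pmid":, "title":, "abstract":, "journal":, "pub_date":, "mentions":
#' [{"text":, "class":, "id":, "start":, "end":}]}` — the consumed dialect of
#' a neural NER annotator's output. Mentions lacking a normalised `id` are
#' retained with `concept_id` absent. A record whose pmid is not a positive
#' integer is rejected with a warning; an empty stream yields an empty list.
#'
#' @inheritParams read_pubtator
#' @return List of [annotated_article()] objects.
#' @export
read_annotation_records <- function(path) {
  lines <- read_source_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  articles <- list()
  for (k in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[k], simplifyVector = TRUE),
                    error = function(e) NULL)
    pmid <- suppressWarnings(as.integer(rec$pmid))
    if (is.null(rec) || length(pmid) != 1L || is.na(pmid) || pmid <= 0L) {
      warning("record ", k, " rejected: missing or non-integer pmid")
      next
    }
    men <- rec$mentions
    mentions <- if (!is.null(men) && NROW(men) > 0L) {
      men <- data.table::as.data.table(men)
      if (!"id" %in% names(men)) men$id <- NA_character_
      mention_table(men$text, men$class, men$id, men$start, men$end)
    } else mention_table()
    articles[[length(articles) + 1L]] <- annotated_article(
      pmid, mentions,
      title = rec$title %||% "", abstract = rec$abstract %||% "",
      journal = rec$journal %||% NA_character_,
      pub_date = rec$pub_date %||% NA_character_)
  }
  articles
}

#' Write line-delimited annotation records
#'
#' @inheritParams write_pubtator
#' @export
write_annotation_records <- function(articles, path) {
  lines <- vapply(articles, function(art) {
    m <- art$mentions
    mentions <- if (nrow(m)) {
      lapply(seq_len(nrow(m)), function(i) {
        rec <- list(text = m$surface_text[i], class = m$entity_class[i],
                    start = m$span_start[i], end = m$span_end[i])
        if (!is.na(m$concept_id[i])) rec$id <- m$concept_id[i]
        rec
      })
    } else list()
    rec <- list(pmid = art$pmid, title = art$title, abstract = art$abstract,
                mentions = mentions)
    if (!is.na(art$journal)) rec$journal <- art$journal
    if (!is.na(art$pub_date)) rec$pub_date <- art$pub_date
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
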