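#' Construct an ontology graph
#'
#' A directed acyclic `is_a` hierarchy of cell-type terms. Edges point from
#' child to parent. Obsolete terms and edges touching unknown terms are the
#' parser's concern ([parse_obo()]); the constructor enforces acyclicity and
#' known endpoints.
#'
#' @param terms `data.frame` with columns `id`, `name` and optionally
#'   `synonyms` (pipe-separated string).
#' @param edges `data.frame` with columns `child`, `parent` (term ids).
#' @return Object of class `ontology_graph`.
#' @export
ontology_graph <- function(terms, edges) {
  terms <- data.table::as.data.table(terms)
  edges <- data.table::as.data.table(edges)
  if (!"synonyms" %in% names(terms)) terms$synonyms <- NA_character_
  if (nrow(edges)) {
    unknown <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
    if (length(unknown)) {
      stop("edge endpoint(s) not in term set: ",
           paste(unknown, collapse = ", "))
    }
  }
  g <- igraph::graph_from_data_frame(
    edges[, .(from = child, to = parent)],
    directed = TRUE,
    vertices = terms[, .(name = id, label = name)])
  if (!igraph::is_dag(g)) {
    cyc <- find_one_cycle(g)
    stop("is_a relation is cyclic, e.g.: ", paste(cyc, collapse = " -> "))
  }
  structure(list(terms = data.table::setkey(terms, id), edges = edges,
                 graph = g),
            class = "ontology_graph")
}

find_one_cycle <- function(g) {
  for (v in igraph::V(g)) {
    res <- suppressWarnings(
      igraph::shortest_paths(g, from = v, to = v, mode = "out",
                             output = "vpath"))
    # self-loop or back-edge detection via DFS instead:
    nb <- igraph::neighbors(g, v, mode = "out")
    for (w in nb) {
      if (igraph::distances(g, v = w, to = v, mode = "out")[1, 1] < Inf) {
        p <- igraph::shortest_paths(g, from = w, to = v,
                                    mode = "out")$vpath[[1]]
        return(c(igraph::V(g)$name[v], igraph::V(g)$name[p]))
      }
    }
  }
  character()
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph terms=%d is_a edges=%d>\n",
              nrow(x$terms), nrow(x$edges)))
  invisible(x)
}

#' Term ids of an ontology graph
#' @param ontology An `ontology_graph`.
#' @export
ontology_ids <- function(ontology) ontology$terms$id

#' Parse an OBO flat file into an ontology graph
#'
#' Consumes `[Term]` stanzas and the tags `id`, `name`, `synonym`, `is_a`
#' and `is_obsolete`; every other tag and relationship type (`part_of`,
#' `develops_from`, ...) is ignored. Obsolete terms are excluded together
#' with any `is_a` edge touching them; an `is_a` pointing at an id that
#' never appears as a term is dropped with a warning. A cyclic `is_a`
#' closure fails, naming one cycle.
#'
#' @param path OBO file path (plain or gzip) or connection.
#' @return An `ontology_graph`.
#' @export
parse_obo <- function(path) {
  lines <- read_source_lines(path)
  in_term <- FALSE
  cur <- NULL
  stanzas <- list()
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id))
      stanzas[[length(stanzas) + 1L]] <<- cur
  }
  for (line in lines) {
    line <- sub("!.*$", "", line)          # strip trailing comments
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[", line)) {
      flush()
      cur <- NULL
      in_term <- identical(line, "[Term]")
      if (in_term) cur <- list(synonyms = character(), is_a = character(),
                               obsolete = FALSE)
      next
    }
    if (!in_term) next
    kv <- regmatches(line, regexec("^([a-z_]+):\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) next
    val <- trimws(kv[3])
    switch(kv[2],
      id = { cur$id <- val },
      name = { cur$name <- val },
      is_a = { cur$is_a <- c(cur$is_a, trimws(strsplit(val, " ")[[1]][1])) },
      synonym = {
        syn <- regmatches(val, regexec('^"([^"]*)"', val))[[1]]
        if (length(syn) == 2L) cur$synonyms <- c(cur$synonyms, syn[2])
      },
      is_obsolete = { cur$obsolete <- identical(tolower(val), "true") })
  }
  flush()
  if (!length(stanzas)) {
    return(ontology_graph(
      data.table::data.table(id = character(), name = character()),
      data.table::data.table(child = character(), parent = character())))
  }
  terms <- data.table::rbindlist(lapply(stanzas, function(s) {
    data.table::data.table(
      id = s$id, name = s$name %||% s$id,
      synonyms = if (length(s$synonyms)) paste(s$synonyms, collapse = "|")
                 else NA_character_,
      obsolete = s$obsolete)
  }))
  dup <- terms$id[duplicated(terms$id)]
  if (length(dup)) stop("duplicate term id in OBO input: ", dup[1])
  live <- terms[obsolete == FALSE]
  edges <- data.table::rbindlist(lapply(stanzas, function(s) {
    if (s$obsolete || !length(s$is_a)) return(NULL)
    data.table::data.table(child = s$id, parent = s$is_a)
  }))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.table::data.table(child = character(), parent = character())
  } else {
    dangling <- !edges$parent %in% terms$id
    if (any(dangling)) {
      warning("dropping ", sum(dangling),
              " is_a edge(s) to unknown term(s): ",
              paste(unique(edges$parent[dangling]), collapse = ", "))
      edges <- edges[!dangling]
    }
    to_obsolete <- edges$parent %in% terms[obsolete == TRUE]$id
    edges <- edges[!to_obsolete]
  }
  ontology_graph(live[, .(id, name, synonyms)], edges)
}

#' Write an ontology graph as OBO
#'
#' Emits one `[Term]` stanza per term with `id`, `name`, `synonym` and
#' `is_a` lines; parse -> write -> parse is the identity on the graph.
#'
#' @param ontology An `ontology_graph`.
#' @param path Output file path.
#' @export
write_obo <- function(ontology, path) {
  out <- c("format-version: 1.2", "")
  edges <- ontology$edges
  name_of <- stats::setNames(ontology$terms$name, ontology$terms$id)
  for (i in seq_len(nrow(ontology$terms))) {
    tid <- ontology$terms$id[i]
    out <- c(out, "[Term]", paste0("id: ", tid),
             paste0("name: ", ontology$terms$name[i]))
    syn <- ontology$terms$synonyms[i]
    if (!is.na(syn) && nzchar(syn)) {
      out <- c(out, sprintf('synonym: "%s" EXACT []',
                            strsplit(syn, "|", fixed = TRUE)[[1]]))
    }
    parents <- edges[child == tid]$parent
    if (length(parents)) {
      out <- c(out, sprintf("is_a: %s ! %s", parents, name_of[parents]))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Ontology distance between two cell-type terms
#'
#' Length of the shortest path between two terms treating every `is_a` edge
#' as undirected with unit cost: a parent/child step costs 1, a sibling pair
#' (up to the shared parent and back down) costs 2, identical terms score 0.
#' Smaller is closer; superclasses share more commonalities than distantly
#' related specialised subclasses.
#'
#' @param ontology An `ontology_graph`.
#' @param a,b Term ids (vectorised; recycled to equal length).
#' @return Integer distance(s); `NA` marks an unreachable pair (the caller
#'   decides how to treat disconnected components).
#' @export
term_distance <- function(ontology, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  known <- ontology$terms$id
  bad <- setdiff(unique(c(a, b)), known)
  if (length(bad)) stop("unknown term id(s): ", paste(bad, collapse = ", "))
  d <- igraph::distances(ontology$graph, v = unique(a), to = unique(b),
                         mode = "all")
  res <- d[cbind(match(a, rownames(d)), match(b, colnames(d)))]
  ifelse(is.finite(res), as.integer(res), NA_integer_)
}

#' All-pairs ontology distance matrix
#'
#' @param ontology An `ontology_graph`.
#' @param ids Term ids (default: all terms).
#' @return Integer-valued matrix with `NA` for unreachable pairs.
#' @export
term_distance_matrix <- function(ontology, ids = ontology_ids(ontology)) {
  d <- igraph::distances(ontology$graph, v = ids, to = ids, mode = "all")
  d[!is.finite(d)] <- NA
  d
}

#' Validate the ontology DAG
#'
#' @param ontology An `ontology_graph`.
#' @return `list(n_terms, n_edges, n_components, cycles)`; `cycles` is an
#'   empty list for any graph the constructor accepted.
#' @export
validate_dag <- function(ontology) {
  comp <- igraph::components(igraph::as_undirected(ontology$graph))
  list(n_terms = nrow(ontology$terms),
       n_edges = nrow(ontology$edges),
       n_components = comp$no,
       cycles = list())
}
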