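#' Log-normalised relation relevance score
#'
#' The atlas ranks a gene/cell-type relation by
#' `log10(c_pmid) * log10(c_total)`: the number of distinct articles that
#' mention the pair and the total number of co-occurrences across them,
#' combined logarithmically so that heavily studied terms do not swamp the
#' ranking while broad literature support still counts. Contrast with
#' TF-IDF ([tfidf_aggregate()]), which penalises terms precisely because
#' they appear in many documents.
#'
#' @param c_pmid Count of distinct supporting articles (>= 1), vectorised.
#' @param c_total Total co-occurrences over those articles
#'   (`c_total >= c_pmid`), vectorised.
#' @return Non-negative numeric score(s) at full precision; use
#'   [format_score()] for the 2-decimal display convention.
#' @examples
#' relation_score(110, 222)   # 4.79 at 2-decimal display
#' relation_score(10, 10)     # exactly 1
#' @export
relation_score <- function(c_pmid, c_total) {
  if (any(c_pmid < 1)) stop("c_pmid must be >= 1")
  if (any(c_total < c_pmid)) stop("c_total must be >= c_pmid")
  log10(c_pmid) * log10(c_total)
}

#' Display-round a score
#'
#' Presentation is separate from computation: scores are stored at full
#' precision and displayed at 2 decimals with round-half-to-even.
#'
#' @param score Numeric score(s).
#' @param digits Display digits (default 2).
#' @return Numeric, rounded.
#' @export
format_score <- function(score, digits = 2L) round(score, digits)

#' Aggregated TF-IDF comparator
#'
#' Classical term-frequency x inverse-document-frequency transferred to an
#' aggregated relation: term frequency is the total co-occurrence count and
#' document frequency the number of distinct supporting articles out of a
#' corpus of `n_documents`. The default variant is
#' `c_total * log10(D / c_pmid)`; `log_tf` replaces the tf term with
#' `1 + log10(c_total)` and `smoothed_idf` uses `log10(1 + D / c_pmid)`.
#' A relation present in every document scores 0 under the default variant.
#'
#' @param c_total,c_pmid Aggregated counts (see [relation_score()]).
#' @param n_documents Corpus document count `D`; must be >= `c_pmid`.
#' @param variant TF-IDF variant.
#' @return Non-negative numeric score(s).
#' @export
tfidf_aggregate <- function(c_total, c_pmid, n_documents,
                            variant = c("raw", "log_tf", "smoothed_idf")) {
  variant <- match.arg(variant)
  if (any(c_pmid > n_documents)) {
    stop("c_pmid cannot exceed the corpus document count")
  }
  if (any(c_pmid < 1)) stop("c_pmid must be >= 1")
  tf <- switch(variant, log_tf = 1 + log10(c_total), c_total)
  idf <- switch(variant,
                smoothed_idf = log10(1 + n_documents / c_pmid),
                log10(n_documents / c_pmid))
  tf * idf
}

#' Normalise a score column
#'
#' @param rows `data.table` with a `score` column, or a numeric vector.
#' @param mode `"none"` (identity), `"max"` (divide by the maximum) or
#'   `"minmax"` (affine map to `[0, 1]`; all-equal scores map to 0).
#' @return Same shape as the input with scores normalised; rank order is
#'   preserved.
#' @export
normalize_scores <- function(rows, mode = c("none", "max", "minmax")) {
  mode <- match.arg(mode)
  if (mode == "none") return(rows)
  is_dt <- is.data.frame(rows)
  s <- if (is_dt) rows$score else rows
  if (length(s) == 0L) stop("cannot normalise an empty score set")
  s_new <- switch(mode,
    max = s / max(s),
    minmax = if (max(s) == min(s)) rep(0, length(s))
             else (s - min(s)) / (max(s) - min(s)))
  if (!is_dt) return(s_new)
  out <- data.table::copy(data.table::as.data.table(rows))
  out[, score := s_new][]
}
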