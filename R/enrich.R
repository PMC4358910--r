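# Hypergeometric GO-term enrichment of a query set against a customized
# annotated reference, with Benjamini-Yekutieli adjustment (valid under
# arbitrary dependence among terms). One-sided, enrichment only.

#' Build a GO annotation map
#'
#' @param x Either a two-column data frame (sequence id, GO term) or the
#'   path to a two-column TSV with one id/term pair per line (no header).
#' @return A named list mapping each sequence id to its unique set of GO
#'   term ids. Terms must match `GO:NNNNNNN`; ids without any valid term
#'   are not stored.
#' @export
go_annotation_map <- function(x) {
  if (is.character(x) && length(x) == 1L)
    x <- read.table(x, sep = "\t", header = FALSE,
                    col.names = c("id", "term"),
                    stringsAsFactors = FALSE)
  stopifnot(ncol(x) >= 2)
  ids <- as.character(x[[1]]); terms <- as.character(x[[2]])
  ok <- grepl("^GO:[0-9]{7}$", terms)
  if (!all(ok)) stop("malformed GO term id: ", terms[!ok][1])
  ann <- lapply(split(terms, ids), unique)
  ann[lengths(ann) > 0]
}

#' Benjamini-Yekutieli adjustment
#'
#' FDR adjustment valid under arbitrary dependence: with m tests and
#' c(m) = sum(1/i, i = 1..m), the adjusted value at rank r is
#' min(1, cummin over ranks >= r of p * m * c(m) / r). Input order is
#' preserved in the output.
#'
#' @param p_values Numeric vector of raw p values in (0, 1].
#' @return Adjusted values, elementwise >= the raw values and <= 1.
#' @export
adjust_benjamini_yekutieli <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p values must lie in (0, 1]")
  p.adjust(p_values, method = "BY")
}

#' Hypergeometric GO enrichment of a query set against a reference
#'
#' For each GO term mapped by at least `min_mapping` query entries, the
#' upper-tail hypergeometric probability of observing at least k annotated
#' query entries is computed (k of n query entries vs K of N reference
#' entries), and the tested family is Benjamini-Yekutieli-adjusted.
#'
#' @param query Character vector of query ids; must be a subset of
#'   `reference`.
#' @param reference Character vector of reference ids (the annotated
#'   background). Ids without annotation are dropped with a message.
#' @param ann Annotation map from [go_annotation_map()].
#' @param min_mapping Minimum number of query entries mapping to a term for
#'   it to be tested (applied to the query side; configurable via
#'   `min_mapping_side`).
#' @param alpha Significance level on the adjusted values.
#' @param min_mapping_side `"query"` (default) or `"reference"`.
#' @return A `go_enrichment` data frame with term, k, K, n, N, p_raw,
#'   p_adj and significant, sorted by p_adj.
#' @export
hypergeometric_enrichment <- function(query, reference, ann,
                                      min_mapping = 4, alpha = 0.05,
                                      min_mapping_side = c("query",
                                                           "reference")) {
  min_mapping_side <- match.arg(min_mapping_side)
  query <- unique(query); reference <- unique(reference)
  if (!all(query %in% reference))
    stop("query must be a subset of the reference")
  annotated <- reference[reference %in% names(ann)]
  dropped <- length(reference) - length(annotated)
  if (dropped > 0)
    message(dropped, " reference id(s) without annotation dropped")
  q_ann <- query[query %in% annotated]
  N <- length(annotated); n <- length(q_ann)
  empty <- data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_raw = numeric(0),
                      p_adj = numeric(0), significant = logical(0))
  class(empty) <- c("go_enrichment", "data.frame")
  if (n == 0) return(empty)

  ref_terms <- ann[annotated]
  K_tab <- table(unlist(ref_terms, use.names = FALSE))
  k_tab <- table(unlist(ann[q_ann], use.names = FALSE))
  side <- if (min_mapping_side == "query") k_tab else K_tab[names(k_tab)]
  tested <- names(k_tab)[as.integer(side) >= min_mapping]
  if (length(tested) == 0) return(empty)
  k <- as.integer(k_tab[tested])
  K <- as.integer(K_tab[tested])
  p_raw <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  p_adj <- adjust_benjamini_yekutieli(pmin(p_raw, 1))
  out <- data.frame(term = tested, k = k, K = K, n = n, N = N,
                    p_raw = p_raw, p_adj = p_adj,
                    significant = p_adj <= alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$p_raw, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("go_enrichment", "data.frame")
  out
}

#' @export
print.go_enrichment <- function(x, ...) {
  cat("GO enrichment:", nrow(x), "terms tested,", sum(x$significant),
      "significant\n")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10), digits = 4)
  invisible(x)
}
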