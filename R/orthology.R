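# Reciprocal-best-hit ortholog identification and similarity-distribution
# analysis. The "similarity" of a pair is the percent identity of the
# best supporting HSP in the A-to-B search direction.

.best_hits <- function(hsps) {
  # hsp_table is already canonically sorted: query, bit desc, aln_len desc,
  # subject id; the first row per query is its unique best hit.
  hsps[!duplicated(hsps$query_id), , drop = FALSE]
}

#' Reciprocal-best-hit ortholog pairs
#'
#' A pair (a, b) is reported iff b is a's best hit in the A-to-B search and
#' a is b's best hit in the B-to-A search (best by bit score; ties broken
#' by lower e-value, longer alignment, then lexicographic subject id, as
#' guaranteed by the `hsp_table` ordering).
#'
#' @param hits_ab,hits_ba `hsp_table`s from the two search directions, both
#'   already filtered at the e-value threshold.
#' @param a_class Optional named character vector mapping A-side ids to
#'   `"isotig"` or `"singleton"`. By default ids containing `"singleton"`
#'   are classed as singletons.
#' @param known_a,known_b Optional character vectors of valid ids; hits
#'   referencing unknown ids raise an error.
#' @return An `ortholog_pairs` data frame with `id_a`, `id_b`, `similarity`
#'   (percent identity of the supporting A-to-B HSP), `a_class`, and the
#'   supporting HSP columns prefixed `hsp_`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, a_class = NULL,
                                 known_a = NULL, known_b = NULL) {
  if (!is.null(known_a)) {
    bad <- setdiff(c(hits_ab$query_id, hits_ba$subject_id), known_a)
    if (length(bad)) stop("hit references unknown A-side id: ", bad[1])
  }
  if (!is.null(known_b)) {
    bad <- setdiff(c(hits_ab$subject_id, hits_ba$query_id), known_b)
    if (length(bad)) stop("hit references unknown B-side id: ", bad[1])
  }
  ab <- .best_hits(hits_ab)
  ba <- .best_hits(hits_ba)
  back <- ba$subject_id[match(ab$subject_id, ba$query_id)]
  keep <- !is.na(back) & back == ab$query_id
  ab <- ab[keep, , drop = FALSE]
  cls <- if (is.null(a_class))
    ifelse(grepl("singleton", ab$query_id, fixed = TRUE), "singleton",
           "isotig")
  else unname(a_class[ab$query_id])
  out <- data.frame(id_a = ab$query_id, id_b = ab$subject_id,
                    similarity = ab$pident, a_class = cls,
                    stringsAsFactors = FALSE)
  hsp_cols <- c("strand", "q_start", "q_end", "s_start", "s_end",
                "raw_score", "bit_score", "evalue", "n_identical", "aln_len")
  for (cn in hsp_cols) out[[paste0("hsp_", cn)]] <- ab[[cn]]
  out <- out[order(out$id_a), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ortholog_pairs", "data.frame")
  out
}

#' Percent-identity distribution of ortholog pairs
#'
#' Bins pair similarities into 1%-wide intervals \[x, x+1) for integer x in
#' 0..99 (a similarity of exactly 100 falls in the last bin \[99, 100\]),
#' with subtotals by A-side class.
#'
#' @param pairs An `ortholog_pairs` data frame.
#' @return A `similarity_histogram` list with `bin_lower`, `counts`,
#'   `by_class`, `median`, `mean`, and `n`. An empty input yields the
#'   empty-histogram sentinel (`n = 0`, all counts zero, `NA` median).
#' @export
similarity_histogram <- function(pairs) {
  bins <- 0:99
  if (nrow(pairs) == 0) {
    h <- list(bin_lower = bins, counts = setNames(integer(100), bins),
              by_class = matrix(0L, 2, 100,
                                dimnames = list(c("isotig", "singleton"),
                                                bins)),
              median = NA_real_, mean = NA_real_, n = 0L)
    class(h) <- "similarity_histogram"
    return(h)
  }
  stopifnot(all(pairs$similarity >= 0 & pairs$similarity <= 100))
  b <- pmin(floor(pairs$similarity), 99)
  counts <- table(factor(b, levels = bins))
  by_class <- table(factor(pairs$a_class, levels = c("isotig", "singleton")),
                    factor(b, levels = bins))
  h <- list(bin_lower = bins,
            counts = setNames(as.integer(counts), bins),
            by_class = matrix(as.integer(by_class), 2, 100,
                              dimnames = list(c("isotig", "singleton"),
                                              bins)),
            median = median(pairs$similarity),
            mean = mean(pairs$similarity), n = nrow(pairs))
  class(h) <- "similarity_histogram"
  h
}

#' @export
print.similarity_histogram <- function(x, ...) {
  cat("Similarity histogram:", x$n, "pairs; median",
      format(x$median, digits = 4), "; mean", format(x$mean, digits = 4),
      "\n")
  occ <- x$counts[x$counts > 0]
  if (length(occ)) {
    cat("Occupied bins (lower edge: count):\n")
    print(occ)
  }
  invisible(x)
}

#' Select the most conserved ortholog pairs
#'
#' Keeps pairs with similarity strictly above `threshold` percent. When
#' `isotigs_only` is set (the default), pairs whose A-side member is a
#' singleton are excluded first, since short fragments only reflect local,
#' not gene-wide, similarity.
#'
#' @param pairs An `ortholog_pairs` data frame.
#' @param threshold Percent-identity cutoff in (0, 100); strict inequality.
#' @param isotigs_only Drop singleton-containing pairs first.
#' @return The selected subset, same class as the input.
#' @export
select_conserved <- function(pairs, threshold = 93, isotigs_only = TRUE) {
  stopifnot(threshold >= 0, threshold < 100)
  if (isotigs_only) pairs <- pairs[pairs$a_class != "singleton", ,
                                   drop = FALSE]
  out <- pairs[pairs$similarity > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write ortholog pairs and histograms as TSV
#'
#' @param pairs An `ortholog_pairs` data frame.
#' @param hist A `similarity_histogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  write.table(as.data.frame(pairs)[, c("id_a", "id_b", "similarity",
                                       "a_class")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs_tsv
#' @export
write_histogram_tsv <- function(hist, path) {
  df <- data.frame(bin_lower = hist$bin_lower,
                   count = unname(hist$counts),
                   isotig = hist$by_class["isotig", ],
                   singleton = hist$by_class["singleton", ])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
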