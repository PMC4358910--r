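# Presence/absence calling of reference protein-coding genes in a
# transcriptome via translated reciprocal search (TBLASTN-like forward,
# BLASTX-like reverse), and the two-species concordance table.
# The calls carry transcript evidence only: absence of an ortholog in a
# transcriptome is, by itself, not evidence of absence in the genome.

#' Call presence/absence of reference genes in a transcriptome
#'
#' Forward search: each reference protein against six-frame translations
#' of the transcripts. Reverse search: transcript translations against the
#' protein set. A gene is called present iff its forward best hit passes
#' the e-value threshold and the best reverse hit of that transcript
#' returns the same reference gene (reciprocity; configurable to
#' forward-only for sensitivity analysis).
#'
#' @param ref_proteins Named character vector of reference protein
#'   sequences.
#' @param transcripts Named character vector of nucleotide transcripts.
#' @param params A [search_params()].
#' @param require_reciprocal Require the reverse best hit to agree
#'   (default TRUE).
#' @return A `presence_calls` data frame: ref_gene_id, status
#'   (present/absent), best_transcript, evalue, reciprocal_ok,
#'   n_supporting (transcripts passing the forward threshold with
#'   reciprocal agreement, for duplication reporting), orf_complete and
#'   the evidence caveat column `transcript_evidence_only`.
#' @export
call_gene_presence <- function(ref_proteins, transcripts,
                               params = search_params(),
                               require_reciprocal = TRUE) {
  stopifnot(length(ref_proteins) > 0, length(transcripts) > 0)
  fwd <- search_translated("protein-query-vs-nt-db", ref_proteins,
                           transcripts, params)
  rev <- search_translated("protein-db-vs-nt-query", transcripts,
                           ref_proteins, params)
  rev_best <- .best_hits(rev)
  rev_map <- setNames(rev_best$subject_id, rev_best$query_id)
  calls <- lapply(names(ref_proteins), function(g) {
    h <- fwd[fwd$query_id == g, , drop = FALSE]
    if (nrow(h) == 0)
      return(data.frame(ref_gene_id = g, status = "absent",
                        best_transcript = NA_character_,
                        evalue = NA_real_, reciprocal_ok = FALSE,
                        n_supporting = 0L, orf_complete = NA,
                        stringsAsFactors = FALSE))
    recip <- unname(rev_map[h$subject_id]) == g
    recip[is.na(recip)] <- FALSE
    qualifying <- if (require_reciprocal) h[recip, , drop = FALSE] else h
    if (nrow(qualifying) == 0)
      return(data.frame(ref_gene_id = g, status = "absent",
                        best_transcript = NA_character_,
                        evalue = NA_real_, reciprocal_ok = FALSE,
                        n_supporting = 0L, orf_complete = NA,
                        stringsAsFactors = FALSE))
    best <- qualifying[1, ]    # hsp_table order: best bit score first
    orf <- find_longest_orf(transcripts[[best$subject_id]])
    data.frame(ref_gene_id = g, status = "present",
               best_transcript = best$subject_id, evalue = best$evalue,
               reciprocal_ok = TRUE,
               n_supporting = length(unique(qualifying$subject_id)),
               orf_complete = orf$complete, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  out$transcript_evidence_only <- TRUE
  class(out) <- c("presence_calls", "data.frame")
  out
}

#' Two-species presence/absence concordance table
#'
#' @param calls_a,calls_b `presence_calls` over the same gene panel.
#' @return A `concordance_table` list with the 2x2 counts
#'   (absent_both, present_both, present_a_only, present_b_only) and the
#'   panel size.
#' @export
concordance_table <- function(calls_a, calls_b) {
  if (!setequal(calls_a$ref_gene_id, calls_b$ref_gene_id))
    stop("gene panels differ between the two call sets")
  b <- calls_b[match(calls_a$ref_gene_id, calls_b$ref_gene_id), ]
  pa <- calls_a$status == "present"
  pb <- b$status == "present"
  structure(list(absent_both = sum(!pa & !pb),
                 present_both = sum(pa & pb),
                 present_a_only = sum(pa & !pb),
                 present_b_only = sum(!pa & pb),
                 panel_size = nrow(calls_a)),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Presence/absence concordance over", x$panel_size, "genes\n")
  m <- matrix(c(x$present_both, x$present_a_only, x$present_b_only,
                x$absent_both), 2, 2,
              dimnames = list(A = c("present", "absent"),
                              B = c("present", "absent")))
  print(m)
  invisible(x)
}

#' @rdname concordance_table
#' @param x A `concordance_table`.
#' @param path Output TSV path.
#' @export
write_concordance_tsv <- function(x, path) {
  df <- data.frame(absent_both = x$absent_both,
                   present_both = x$present_both,
                   present_a_only = x$present_a_only,
                   present_b_only = x$present_b_only,
                   panel_size = x$panel_size)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
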