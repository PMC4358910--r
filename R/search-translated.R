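# Translated similarity search: the nucleotide side is translated in all
# six reading frames, stop codons split each frame into segments, and the
# protein side is aligned against the segments with a BLOSUM matrix.
# HSPs carry protein coordinates on the protein side and nucleotide
# coordinates (plus the frame) on the nucleotide side.

# Translate one nucleotide sequence in all six frames and cut at stops.
# Returns a data.frame of stop-free segments with the protein sequence and
# the frame (+1..+3, -1..-3) plus the 0-based offset (in aa) of the segment
# within its frame translation.
.genetic_code_cache <- new.env(parent = emptyenv())
.gc_table <- function() {
  if (is.null(.genetic_code_cache$gc))
    .genetic_code_cache$gc <- Biostrings::GENETIC_CODE
  .genetic_code_cache$gc
}

.six_frame_segments <- function(seq, min_seg = 10L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 3L) {
    warning("nucleotide sequence shorter than 3 nt skipped")
    return(data.frame(frame = integer(0), offset = integer(0),
                      aa = character(0)))
  }
  gc <- .gc_table()
  rc <- revcomp(seq)
  fr_v <- integer(0); off_v <- integer(0); aa_seg <- character(0)
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    s <- if (fr > 0) seq else rc
    off <- abs(fr) - 1L
    len <- ((n - off) %/% 3L) * 3L
    if (len < 3L) next
    st <- seq.int(off + 1L, off + len, by = 3L)
    aa_v <- unname(gc[substring(s, st, st + 2L)])
    aa_v[is.na(aa_v)] <- "X"     # ambiguous codons
    aa <- paste(aa_v, collapse = "")
    # split at stops into maximal stop-free runs
    runs <- gregexpr("[^*]+", aa)[[1]]
    if (runs[1] == -1) next
    w <- attr(runs, "match.length")
    keep <- which(w >= min_seg)
    if (!length(keep)) next
    fr_v <- c(fr_v, rep.int(fr, length(keep)))
    off_v <- c(off_v, runs[keep] - 1L)
    aa_seg <- c(aa_seg, substring(aa, runs[keep], runs[keep] + w[keep] - 1L))
  }
  data.frame(frame = fr_v, offset = off_v, aa = aa_seg,
             stringsAsFactors = FALSE)
}

# Convert a 0-based half-open interval on a frame segment (aa units) to a
# 0-based half-open nucleotide interval on the original sequence.
.segment_to_nt <- function(frame, offset, aa_start, aa_end, nt_len) {
  p0 <- offset + aa_start          # aa position within the frame, 0-based
  p1 <- offset + aa_end
  f0 <- abs(frame) - 1L
  if (frame > 0) c(f0 + 3L * p0, f0 + 3L * p1)
  else c(nt_len - (f0 + 3L * p1), nt_len - (f0 + 3L * p0))
}

# BLOSUM neighbourhood expander for protein seed words: maps a query k-mer
# to all words scoring >= params$neighbor_threshold against it under the
# substitution matrix (vectorised over the full 20^k score array for k = 3;
# memoised per k-mer). Only k = 3 neighbourhood seeding is supported;
# other word sizes fall back to exact-word seeding.
.neighbor_expander <- function(params, mat, k) {
  std <- .AA_ALPHABET[1:20]
  sub <- mat[std, std, drop = FALSE]
  thr <- params$neighbor_threshold
  cache <- new.env(hash = TRUE)
  if (k != 3L) return(function(kmer) kmer)
  words3 <- as.vector(outer(outer(std, std, paste0), std, paste0))
  # words3[i + 20*j + 400*l + 1] = paste0(std[i+1], std[j+1], std[l+1])
  function(kmer) {
    hit <- cache[[kmer]]
    if (!is.null(hit)) return(hit)
    aa <- substring(kmer, 1:3, 1:3)
    if (any(!aa %in% std)) {
      cache[[kmer]] <- character(0)
      return(character(0))
    }
    sc <- outer(outer(sub[aa[1], ], sub[aa[2], ], "+"), sub[aa[3], ], "+")
    words <- words3[which(sc >= thr)]
    cache[[kmer]] <- words
    words
  }
}

#' Translated similarity search (BLASTX / TBLASTN style)
#'
#' Aligns protein sequences against six-frame translations of nucleotide
#' sequences. In mode `"protein-query-vs-nt-db"` (TBLASTN-like) the queries
#' are proteins and the subjects nucleotide; in `"protein-db-vs-nt-query"`
#' (BLASTX-like) the queries are nucleotide and the subjects proteins.
#' Scoring uses `params$protein_matrix`; stop codons split frames into
#' segments that are searched independently.
#'
#' @param mode Search direction (see above).
#' @param queries,subjects Named character vectors.
#' @param params A [search_params()] object.
#' @return A `hsp_table` with an extra `frame` column; coordinates on the
#'   protein side are in residues, on the nucleotide side in nucleotides
#'   (both 0-based half-open on the original input sequences), `strand`
#'   reflects the sign of the frame of the nucleotide side.
#' @export
search_translated <- function(mode = c("protein-query-vs-nt-db",
                                       "protein-db-vs-nt-query"),
                              queries, subjects, params = search_params()) {
  mode <- match.arg(mode)
  if (is.null(names(queries)) || is.null(names(subjects)))
    stop("queries and subjects must be named")
  prot_is_query <- mode == "protein-query-vs-nt-db"
  prots <- if (prot_is_query) queries else subjects
  nts <- if (prot_is_query) subjects else queries
  k <- .word_size(params, "protein")
  mat <- .protein_score_matrix(params$protein_matrix)

  # translate the nucleotide side into indexed stop-free segments
  segs <- lapply(nts, .six_frame_segments)
  seg_tab <- do.call(rbind, Map(function(id, df) {
    if (nrow(df)) df$nt_id <- id
    df
  }, names(nts), segs))
  if (is.null(seg_tab) || nrow(seg_tab) == 0L) return(.empty_hsps(frame = TRUE))
  seg_tab$seg_id <- sprintf("seg%06d", seq_len(nrow(seg_tab)))
  seg_seqs <- setNames(seg_tab$aa, seg_tab$seg_id)

  pp <- params
  pp$word_size <- k
  index <- build_seed_index(seg_seqs, pp, mode = "protein")
  n_db <- sum(nchar(if (prot_is_query) seg_seqs else prots))

  expand <- .neighbor_expander(pp, mat, k)
  res <- list()
  for (qi in seq_along(prots)) {
    min_hits <- if (nchar(prots[[qi]]) - k >= 1L) 2L else 1L
    df <- .extend_query(toupper(prots[[qi]]), index, pp, mat,
                        .AA_AMBIG_FROM, min_hits = min_hits,
                        expand = expand)
    if (is.null(df)) next
    df$prot_id <- names(prots)[qi]
    res[[length(res) + 1L]] <- df
  }
  if (!length(res)) return(.empty_hsps(frame = TRUE))
  df <- do.call(rbind, res)
  seg <- seg_tab[match(index$subject_ids[df$sidx], seg_tab$seg_id), ]
  nt_len <- nchar(nts)[match(seg$nt_id, names(nts))]
  nt_iv <- t(mapply(.segment_to_nt, seg$frame, seg$offset,
                    df$s_start, df$s_end, nt_len))

  out <- data.frame(
    query_id = if (prot_is_query) df$prot_id else seg$nt_id,
    subject_id = if (prot_is_query) seg$nt_id else df$prot_id,
    strand = ifelse(seg$frame > 0, "+", "-"),
    q_start = if (prot_is_query) df$q_start else nt_iv[, 1],
    q_end = if (prot_is_query) df$q_end else nt_iv[, 2],
    s_start = if (prot_is_query) nt_iv[, 1] else df$q_start,
    s_end = if (prot_is_query) nt_iv[, 2] else df$q_end,
    raw_score = df$raw_score, stringsAsFactors = FALSE)
  out$frame <- seg$frame
  out$n_identical <- df$n_identical
  out$aln_len <- df$aln_len
  qlen <- nchar(prots)[match(df$prot_id, names(prots))]
  out$bit_score <- ka_bit_score(out$raw_score, "protein")
  out$evalue <- ka_evalue(out$raw_score, qlen, n_db, "protein")
  out$pident <- 100 * out$n_identical / out$aln_len

  # keep the best extension per (query, subject, strand)
  key <- paste(out$query_id, out$subject_id, out$strand)
  out <- out[order(-out$raw_score), ]
  out <- out[!duplicated(paste(out$query_id, out$subject_id, out$strand)), ]
  out <- out[out$evalue <= params$evalue_threshold, , drop = FALSE]
  if (nrow(out) == 0L) return(.empty_hsps(frame = TRUE))
  .hsp_table(out[, c("query_id", "subject_id", "strand", "q_start", "q_end",
                     "s_start", "s_end", "raw_score", "bit_score", "evalue",
                     "n_identical", "aln_len", "pident", "frame")])
}
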