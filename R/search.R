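# Seed-and-extend local similarity search producing BLAST-like HSPs.
#
# Seeding: exact k-mer hits (nucleotide) or BLOSUM-neighbourhood k-mer hits
# (protein) are grouped per (subject, strand) into diagonal clusters; a
# cluster supported by at least two seeds (the classic two-hit rule; one
# seed suffices for very short queries and in protein mode) triggers gapped
# extension: a banded affine-gap Smith-Waterman restricted to the seeded
# diagonals plus `band` padding. The best-scoring extension per
# (query, subject, strand) is the reported HSP, which makes merging of
# overlapping HSPs to the highest-scoring one automatic.

.seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

#' Build a positional k-mer index over a set of subject sequences
#'
#' @param subjects Named character vector of subject sequences.
#' @param params A [search_params()] object.
#' @param mode `"nucleotide"` or `"protein"`.
#' @return A `seed_index` object. K-mers containing `N` (nucleotide) or
#'   `X`/`*` (protein) are skipped.
#' @export
build_seed_index <- function(subjects, params = search_params(),
                             mode = c("nucleotide", "protein")) {
  mode <- match.arg(mode)
  if (length(subjects) == 0) stop("empty subject set")
  if (is.null(names(subjects)) || anyDuplicated(names(subjects)))
    stop("subjects must be uniquely named")
  k <- .word_size(params, mode)
  subjects <- toupper(subjects)
  km <- lapply(unname(subjects), .seq_kmers, k = k)
  sidx <- rep.int(seq_along(subjects), lengths(km))
  pos <- unlist(lapply(lengths(km), function(n) seq_len(n)), use.names = FALSE)
  km <- unlist(km, use.names = FALSE)
  bad <- if (mode == "nucleotide") grepl("N", km, fixed = TRUE)
         else grepl("[X*]", km)
  if (any(bad)) {
    km <- km[!bad]; sidx <- sidx[!bad]; pos <- pos[!bad]
  }
  groups <- split(seq_along(km), km)
  env <- list2env(groups, hash = TRUE, size = max(1L, length(groups)))
  structure(list(env = env, sidx = sidx, pos = pos, k = k, mode = mode,
                 subject_ids = names(subjects), subjects = unname(subjects),
                 subjects_enc = lapply(unname(subjects), encode_seq, mode),
                 total_len = sum(nchar(subjects))),
            class = "seed_index")
}

#' Look up the indexed positions of one k-mer
#'
#' @param index A `seed_index`.
#' @param kmer A single k-mer.
#' @return Data frame with `subject_id` and 1-based `pos` of every occurrence.
#' @export
seed_lookup <- function(index, kmer) {
  i <- index$env[[toupper(kmer)]]
  if (is.null(i))
    return(data.frame(subject_id = character(0), pos = integer(0)))
  data.frame(subject_id = index$subject_ids[index$sidx[i]],
             pos = index$pos[i], stringsAsFactors = FALSE)
}

# All seed hits of a query against the index: matrix of (subject index,
# subject pos, query pos), 1-based. `expand` maps a query k-mer to the set
# of index words to probe (identity for nucleotide, neighbourhood for
# protein).
.seed_hits <- function(query, index, expand = NULL) {
  km <- .seq_kmers(query, index$k)
  if (length(km) == 0)
    return(matrix(integer(0), 0, 3))
  qpos <- seq_along(km)
  if (!is.null(expand)) {
    probes <- lapply(km, expand)
    qpos <- rep.int(qpos, lengths(probes))
    km <- unlist(probes, use.names = FALSE)
    if (length(km) == 0) return(matrix(integer(0), 0, 3))
  }
  got <- mget(km, envir = index$env, ifnotfound = list(NULL))
  n_hits <- lengths(got)
  keep <- n_hits > 0
  if (!any(keep)) return(matrix(integer(0), 0, 3))
  i <- unlist(got[keep], use.names = FALSE)
  cbind(sidx = index$sidx[i], spos = index$pos[i],
        qpos = rep.int(qpos[keep], n_hits[keep]))
}

# Candidate diagonal clusters of one (query, subject) pair: diagonals
# carrying at least `min_hits` seeds (the two-hit rule applied on the
# diagonal, where colinear homology concentrates its seeds), with nearby
# candidate diagonals (within `gap`, accounting for small indels) merged
# into one extension band.
.diag_clusters <- function(diags, gap, min_hits, max_clusters = 4L) {
  tab <- tabulate(match(diags, unique(diags)))
  ud <- unique(diags)
  d <- sort(ud[tab >= min_hits])
  if (!length(d)) return(list())
  brk <- c(0L, which(diff(d) > gap), length(d))
  cl <- lapply(seq_len(length(brk) - 1L), function(i) {
    dd <- d[(brk[i] + 1L):brk[i + 1L]]
    list(dlo = dd[1], dhi = dd[length(dd)], diags = dd,
         n = sum(diags >= dd[1] & diags <= dd[length(dd)]))
  })
  if (length(cl) > max_clusters) {
    ord <- order(vapply(cl, `[[`, 0L, "n"), decreasing = TRUE)
    cl <- cl[ord[seq_len(max_clusters)]]
  }
  cl
}

# Extend one query against all seeded subjects; returns a data.frame of raw
# HSPs (one best per subject) or NULL. Coordinates are 0-based half-open on
# the (possibly reverse-complemented) query as passed in.
.extend_query <- function(query, index, params, mat, ambig, min_hits,
                          expand = NULL) {
  hits <- .seed_hits(toupper(query), index, expand)
  if (nrow(hits) == 0) return(NULL)
  qa <- encode_seq(toupper(query), index$mode)
  cutoff <- params$ungapped_cutoff %||%
    if (index$mode == "nucleotide") {
      if (length(qa) >= 40L) 30 else 0
    } else {
      if (length(qa) >= 20L) 35 else 0
    }
  by_subj <- split(hits[, "spos"] - hits[, "qpos"], hits[, "sidx"])
  acc <- matrix(0, length(by_subj), 8L)  # sidx, score, q0/q1, s0/s1, nid, alen
  nout <- 0L
  for (si_chr in names(by_subj)) {
    si <- as.integer(si_chr)
    cl <- .diag_clusters(by_subj[[si_chr]], gap = params$band,
                         min_hits = min_hits)
    if (length(cl) == 0) next
    sb <- index$subjects_enc[[si]]
    best <- NULL
    for (x in cl) {
      # ungapped prefilter: the best ungapped run along the seeded
      # diagonals must clear a floor before gapped extension is spent
      if (cutoff > 0 &&
          c_diag_kadane(qa, sb, mat, as.integer(x$diags)) < cutoff) next
      r <- c_sw_align(qa, sb, mat, params$gap_open, params$gap_extend,
                      as.integer(x$dlo - params$band),
                      as.integer(x$dhi + params$band), ambig)
      if (is.null(best) || r$score > best$score) best <- r
    }
    if (is.null(best)) next
    if (best$score <= 0) next
    nout <- nout + 1L
    acc[nout, ] <- c(si, best$score, best$q_begin, best$q_end,
                     best$s_begin, best$s_end, best$n_identical,
                     best$aln_len)
  }
  if (nout == 0L) return(NULL)
  acc <- acc[seq_len(nout), , drop = FALSE]
  data.frame(sidx = as.integer(acc[, 1]), raw_score = acc[, 2],
             q_start = as.integer(acc[, 3]), q_end = as.integer(acc[, 4]),
             s_start = as.integer(acc[, 5]), s_end = as.integer(acc[, 6]),
             n_identical = as.integer(acc[, 7]),
             aln_len = as.integer(acc[, 8]))
}

.hsp_table <- function(df) {
  df <- df[order(df$query_id, -df$bit_score, -df$aln_len, df$subject_id), ,
           drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("hsp_table", "data.frame")
  df
}

.empty_hsps <- function(frame = FALSE) {
  df <- data.frame(query_id = character(0), subject_id = character(0),
                   strand = character(0), q_start = integer(0),
                   q_end = integer(0), s_start = integer(0),
                   s_end = integer(0), raw_score = numeric(0),
                   bit_score = numeric(0), evalue = numeric(0),
                   n_identical = integer(0), aln_len = integer(0),
                   pident = numeric(0))
  if (frame) df$frame <- integer(0)
  .hsp_table(df)
}

#' Nucleotide seed-and-extend search
#'
#' BLASTN-like search of a set of queries against an indexed subject set.
#' Both strands are searched (the reverse complement of the query is
#' seeded and extended; minus-strand HSP query coordinates are mapped back
#' to the original query). Per (query, subject, strand) only the
#' highest-scoring extension is kept, and only HSPs with expectation value
#' at or below `params$evalue_threshold` are returned, sorted by query and
#' decreasing bit score (ties: longer alignment, then subject id).
#'
#' @param queries Named character vector of query sequences.
#' @param index A nucleotide `seed_index` from [build_seed_index()].
#' @param params A [search_params()] object.
#' @return A `hsp_table` data frame with 0-based half-open intervals.
#' @export
search_nucleotide <- function(queries, index, params = search_params()) {
  if (!inherits(index, "seed_index") || index$mode != "nucleotide")
    stop("index must be a nucleotide seed_index")
  if (is.null(names(queries))) stop("queries must be named")
  mat <- .score_matrix(params, "nucleotide")
  n_db <- index$total_len
  res <- vector("list", 2L * length(queries)); nres <- 0L
  for (qi in seq_along(queries)) {
    qseq <- toupper(queries[[qi]])
    qlen <- nchar(qseq)
    min_hits <- if (qlen - index$k >= 1L) 2L else 1L
    for (strand in c("+", "-")) {
      qs <- if (strand == "+") qseq else revcomp(qseq)
      df <- .extend_query(qs, index, params, mat, .DNA_AMBIG_FROM, min_hits)
      if (is.null(df)) next
      if (strand == "-") {
        qs0 <- qlen - df$q_end
        df$q_end <- qlen - df$q_start
        df$q_start <- qs0
      }
      df$query_id <- names(queries)[qi]
      df$subject_id <- index$subject_ids[df$sidx]
      df$strand <- strand
      nres <- nres + 1L
      res[[nres]] <- df
    }
  }
  if (nres == 0L) return(.empty_hsps())
  df <- do.call(rbind, res[seq_len(nres)])
  qlen <- nchar(queries)[match(df$query_id, names(queries))]
  df$bit_score <- ka_bit_score(df$raw_score, "nucleotide")
  df$evalue <- ka_evalue(df$raw_score, qlen, n_db, "nucleotide")
  df$pident <- 100 * df$n_identical / df$aln_len
  df <- df[df$evalue <= params$evalue_threshold, , drop = FALSE]
  if (nrow(df) == 0L) return(.empty_hsps())
  .hsp_table(df[, c("query_id", "subject_id", "strand", "q_start", "q_end",
                    "s_start", "s_end", "raw_score", "bit_score", "evalue",
                    "n_identical", "aln_len", "pident")])
}

#' @export
print.hsp_table <- function(x, ...) {
  cat("HSP table:", nrow(x), "hits,", length(unique(x$query_id)),
      "queries\n")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Write / read HSP tables as BLAST outfmt-6-style TSV
#'
#' Columns follow the tabular BLAST convention (1-based inclusive
#' coordinates on output; converted back to 0-based half-open on input).
#'
#' @param hsps A `hsp_table`.
#' @param path Output/input file path.
#' @return `write_hsp_tsv` returns `path` invisibly; `read_hsp_tsv` returns
#'   a `hsp_table`.
#' @export
write_hsp_tsv <- function(hsps, path) {
  out <- as.data.frame(hsps)
  out$q_start <- out$q_start + 1L
  out$s_start <- out$s_start + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hsp_tsv
#' @export
read_hsp_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  df$q_start <- df$q_start - 1L
  df$s_start <- df$s_start - 1L
  .hsp_table(df)
}
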