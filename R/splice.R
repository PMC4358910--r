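# Isogroup analysis: map isotigs onto a reference gene model, classify
# aligned blocks as exons/introns, call intron retention, infer how many
# loci feed an isogroup, flag chimeric isotigs, and summarize isogroup
# sizes.

#' Longest open reading frame of a DNA sequence
#'
#' Scans both strands in all three frames for the longest complete
#' start-to-stop ORF (ATG through stop codon, inclusive). When no complete
#' ORF exists, the longest stop-free codon stretch is reported with
#' `complete = FALSE`.
#'
#' @param seq DNA sequence (character).
#' @return List with 0-based half-open `interval` on the input sequence,
#'   `strand`, `frame` (1-3), `complete` flag and `length` in nt.
#' @export
find_longest_orf <- function(seq) {
  seq <- toupper(seq)
  L <- nchar(seq)
  best <- NULL          # longest complete ORF
  best_free <- NULL     # longest stop-free stretch (fallback)
  upd <- function(cand, slot) {
    cur <- if (slot == "orf") best else best_free
    if (is.null(cur) || cand$length > cur$length) {
      if (slot == "orf") best <<- cand else best_free <<- cand
    }
  }
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (f in 1:3) {
      len <- ((L - f + 1L) %/% 3L) * 3L
      if (len < 3L) next
      starts <- seq(f, f + len - 3L, 3L)
      cods <- substring(s, starts, starts + 2L)
      nc <- length(cods)
      stops <- which(cods %in% .STOPS)
      bounds <- c(0L, stops, nc + 1L)
      for (i in seq_len(length(bounds) - 1L)) {
        a <- bounds[i] + 1L; b <- bounds[i + 1L] - 1L
        if (a > b) next
        has_stop <- bounds[i + 1L] <= nc
        # complete ORF: first ATG in the segment through the closing stop
        m <- which(cods[a:b] == "ATG")
        if (length(m) && has_stop) {
          ai <- a + m[1] - 1L
          nt0 <- starts[ai] - 1L
          nt1 <- starts[bounds[i + 1L]] + 2L
          iv <- if (strand == "+") c(nt0, nt1) else c(L - nt1, L - nt0)
          upd(list(interval = iv, strand = strand, frame = f,
                   complete = TRUE, length = nt1 - nt0), "orf")
        }
        # stop-free stretch fallback
        nt0 <- starts[a] - 1L
        nt1 <- starts[b] + 2L
        iv <- if (strand == "+") c(nt0, nt1) else c(L - nt1, L - nt0)
        upd(list(interval = iv, strand = strand, frame = f,
                 complete = FALSE, length = nt1 - nt0), "free")
      }
    }
  }
  best %||% best_free %||%
    list(interval = c(0L, 0L), strand = "+", frame = 1L,
         complete = FALSE, length = 0L)
}

#' Map an isotig onto a gene model
#'
#' Each model feature (exon or intron) is locally aligned against the
#' isotig; the highest-scoring colinear non-overlapping chain of feature
#' blocks (monotone in both model order and isotig position) is kept, and
#' per-feature coverage (aligned feature fraction) computed. Isotig spans
#' not covered by any chained block are labelled `unassigned`.
#'
#' @param isotig Isotig sequence (character) or a named length-one vector.
#' @param model A `gene_model`.
#' @param params A [search_params()].
#' @param isotig_id Identifier used in the output.
#' @return A `segment_assignment`: blocks data frame (feature, kind,
#'   index, 0-based half-open isotig and feature intervals, score),
#'   per-feature `coverage`, the isotig sequence and id.
#' @export
map_transcript_to_model <- function(isotig, model,
                                    params = search_params(),
                                    isotig_id = NULL) {
  isotig_id <- isotig_id %||% names(isotig) %||% "isotig"
  isotig <- toupper(unname(isotig))
  feats <- feature_table(model)
  cand <- vector("list", nrow(feats))
  for (i in seq_len(nrow(feats))) {
    fseq <- substr(model$genomic_seq, feats$start[i] + 1L, feats$end[i])
    flen <- nchar(fseq)
    r <- .sw_core(fseq, isotig, params, "nucleotide")
    floor_score <- max(20, ceiling(0.35 * flen)) * params$match
    if (r$score >= floor_score && r$aln_len > 0 &&
        r$n_identical / r$aln_len >= 0.6)
      cand[[i]] <- r
  }
  have <- which(!vapply(cand, is.null, TRUE))
  cov <- setNames(numeric(nrow(feats)), feats$feature)
  blocks <- data.frame(feature = character(0), kind = character(0),
                       index = integer(0), q_start = integer(0),
                       q_end = integer(0), f_start = integer(0),
                       f_end = integer(0), score = numeric(0))
  if (length(have)) {
    # colinear chain: features already in model order; require isotig
    # intervals to increase (small overlaps tolerated, trimmed below)
    ov <- 8L
    nh <- length(have)
    score <- vapply(have, function(i) cand[[i]]$score, 0)
    qs <- vapply(have, function(i) cand[[i]]$s_begin, 0L)
    qe <- vapply(have, function(i) cand[[i]]$s_end, 0L)
    bestv <- score
    prev <- rep(0L, nh)
    for (i in seq_len(nh)) for (j in seq_len(i - 1L)) {
      if (qe[j] - ov <= qs[i] && qs[j] < qs[i] &&
          bestv[j] + score[i] > bestv[i]) {
        bestv[i] <- bestv[j] + score[i]
        prev[i] <- j
      }
    }
    i <- which.max(bestv)
    chain <- integer(0)
    while (i > 0L) { chain <- c(i, chain); i <- prev[i] }
    sel <- have[chain]
    blocks <- do.call(rbind, lapply(seq_along(sel), function(ci) {
      i <- sel[ci]; r <- cand[[i]]
      data.frame(feature = feats$feature[i], kind = feats$kind[i],
                 index = feats$index[i],
                 q_start = r$s_begin, q_end = r$s_end,
                 f_start = r$q_begin, f_end = r$q_end, score = r$score)
    }))
    # trim residual overlaps on the isotig
    if (nrow(blocks) > 1) for (i in 2:nrow(blocks)) {
      cut <- blocks$q_end[i - 1] - blocks$q_start[i]
      if (cut > 0) {
        blocks$q_start[i] <- blocks$q_start[i] + cut
        blocks$f_start[i] <- blocks$f_start[i] + cut
      }
    }
    blocks <- blocks[blocks$q_end > blocks$q_start, , drop = FALSE]
    flen <- feats$end - feats$start
    for (i in seq_len(nrow(blocks))) {
      fi <- match(blocks$feature[i], feats$feature)
      cov[fi] <- cov[fi] +
        (blocks$f_end[i] - blocks$f_start[i]) / flen[fi]
    }
    cov <- pmin(cov, 1)
  }
  # unassigned isotig spans
  covered <- rep(FALSE, nchar(isotig))
  for (i in seq_len(nrow(blocks)))
    covered[(blocks$q_start[i] + 1L):blocks$q_end[i]] <- TRUE
  if (any(!covered)) {
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    una <- which(!r$values & r$lengths >= 10L)
    if (length(una))
      blocks <- rbind(blocks, data.frame(
        feature = "unassigned", kind = "unassigned", index = NA_integer_,
        q_start = starts[una], q_end = ends[una],
        f_start = NA_integer_, f_end = NA_integer_, score = 0))
  }
  blocks <- blocks[order(blocks$q_start), , drop = FALSE]
  rownames(blocks) <- NULL
  structure(list(isotig_id = isotig_id, isotig_seq = isotig,
                 blocks = blocks, coverage = cov,
                 gene_id = model$gene_id),
            class = "segment_assignment")
}

#' @export
print.segment_assignment <- function(x, ...) {
  cat("Segment assignment of", x$isotig_id, "onto", x$gene_id, ":",
      sum(x$blocks$kind != "unassigned"), "feature block(s)\n")
  print.data.frame(x$blocks)
  invisible(x)
}

#' Call retained introns and ORF completeness for one isotig
#'
#' Intron j is retained iff its aligned coverage is at least
#' `min_coverage`. ORF completeness compares the isotig's longest ORF to
#' the model's mature-mRNA ORF: complete means an ATG..stop ORF spanning
#' at least 90% of the mature coding length whose translation ends in the
#' reference C-terminus (an ORF truncated by an intronic stop codon ends
#' in intron-derived residues and is therefore not the correct ORF even
#' when long).
#'
#' @param assignment A `segment_assignment` from
#'   [map_transcript_to_model()].
#' @param model The `gene_model` the isotig was mapped to.
#' @param min_coverage Coverage threshold for calling a feature present.
#' @return A `splice_call`: isotig id, integer `retained_introns`,
#'   `complete_orf` flag and the 0-based half-open `orf_interval`.
#' @export
call_intron_retention <- function(assignment, model, min_coverage = 0.8) {
  feats <- feature_table(model)
  int_feats <- feats$feature[feats$kind == "intron"]
  retained <- which(assignment$coverage[int_feats] >= min_coverage)
  orf <- find_longest_orf(assignment$isotig_seq)
  ref_orf <- find_longest_orf(mature_mrna(model))
  complete <- isTRUE(orf$complete) && isTRUE(ref_orf$complete) &&
    orf$length >= 0.9 * ref_orf$length
  if (complete) {
    prot <- .orf_protein(assignment$isotig_seq, orf)
    ref_prot <- .orf_protein(mature_mrna(model), ref_orf)
    k <- min(10L, nchar(ref_prot))
    complete <- substr(prot, nchar(prot) - k + 1L, nchar(prot)) ==
      substr(ref_prot, nchar(ref_prot) - k + 1L, nchar(ref_prot))
  }
  structure(list(isotig_id = assignment$isotig_id,
                 retained_introns = as.integer(retained),
                 complete_orf = complete,
                 orf_interval = orf$interval),
            class = "splice_call")
}

# translation of an ORF located by find_longest_orf (stop codon dropped)
.orf_protein <- function(seq, orf) {
  nt <- substr(seq, orf$interval[1] + 1L, orf$interval[2])
  if (orf$strand == "-") nt <- revcomp(nt)
  st <- seq(1L, nchar(nt), 3L)
  aa <- unname(Biostrings::GENETIC_CODE[substring(nt, st, st + 2L)])
  aa[is.na(aa)] <- "X"
  sub("\\*$", "", paste(aa, collapse = ""))
}

#' @export
print.splice_call <- function(x, ...) {
  cat("Splice call", x$isotig_id, ": retained introns {",
      paste(x$retained_introns, collapse = ","), "}, complete ORF:",
      x$complete_orf, "\n")
  invisible(x)
}

# single-linkage clustering of sequences at >= identity% (percent identity
# of the best local alignment); returns integer cluster labels
.cluster_identity <- function(seqs, identity, params) {
  n <- length(seqs)
  if (n <= 1L) return(rep(1L, n))
  lab <- seq_len(n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (lab[i] == lab[j]) next
    r <- .sw_core(seqs[i], seqs[j], params, "nucleotide")
    # identity over the shorter sequence, so near-identical full-length
    # variants cluster even when the local alignment trims edges
    pid <- 100 * r$n_identical / min(nchar(seqs[i]), nchar(seqs[j]))
    if (pid >= identity) lab[lab == lab[j]] <- lab[i]
  }
  match(lab, unique(lab))
}

#' Infer the number of loci feeding an isogroup
#'
#' For each exon of the model, the exon-overlapping block sequences from
#' all isotigs are collected and single-linkage clustered at
#' `cluster_identity` percent identity. The locus-count estimate is the
#' maximum per-exon number of sequence-variant clusters. Cluster labels
#' are made comparable across exons by ranking clusters by similarity to
#' the model's exon sequence; an isotig is chimeric iff, over exons with
#' at least two clusters, it draws blocks from two or more different
#' cluster labels.
#'
#' @param isogroup List with `isogroup_id` and named character vector
#'   `isotigs` (or any named character vector of isotig sequences).
#' @param model A `gene_model`.
#' @param params A [search_params()].
#' @param cluster_identity Percent identity for single-linkage clustering.
#' @param min_coverage Minimum exon coverage for a block to enter
#'   clustering.
#' @return A `locus_inference`: `isogroup_id`, `n_loci`,
#'   `exon_variant_counts`, `chimeric_isotigs`, and the per-isotig,
#'   per-exon label matrix `labels`.
#' @export
infer_locus_count <- function(isogroup, model, params = search_params(),
                              cluster_identity = 98, min_coverage = 0.8) {
  if (is.character(isogroup))
    isogroup <- list(isogroup_id = "isogroup", isotigs = isogroup)
  tigs <- isogroup$isotigs
  if (is.null(names(tigs))) names(tigs) <- sprintf("iso%02d", seq_along(tigs))
  asn <- lapply(seq_along(tigs), function(i)
    map_transcript_to_model(tigs[[i]], model, params,
                            isotig_id = names(tigs)[i]))
  mapped <- vapply(asn, function(a) any(a$blocks$kind == "exon"), TRUE)
  if (!any(mapped)) stop("no isotig maps to the model")
  feats <- feature_table(model)
  exons <- feats[feats$kind == "exon", , drop = FALSE]
  ne <- nrow(exons)
  labels <- matrix(NA_integer_, length(tigs), ne,
                   dimnames = list(names(tigs), exons$feature))
  counts <- setNames(integer(ne), exons$feature)
  for (e in seq_len(ne)) {
    fid <- exons$feature[e]
    exseq <- substr(model$genomic_seq, exons$start[e] + 1L, exons$end[e])
    blocks <- lapply(asn, function(a) {
      b <- a$blocks[a$blocks$feature == fid, , drop = FALSE]
      if (nrow(b) == 0 || a$coverage[fid] < min_coverage) return(NULL)
      substr(a$isotig_seq, b$q_start[1] + 1L, b$q_end[nrow(b)])
    })
    have <- which(!vapply(blocks, is.null, TRUE))
    if (!length(have)) next
    seqs <- unlist(blocks[have])
    uniq <- unique(seqs)
    ulab <- .cluster_identity(uniq, cluster_identity, params)
    # rank clusters by their best similarity to the model exon so labels
    # are comparable across exons (1 = closest to the reference model)
    sim <- vapply(seq_along(uniq), function(i) {
      r <- .sw_core(uniq[i], exseq, params, "nucleotide")
      100 * r$n_identical / max(1L, r$aln_len)
    }, 0)
    csim <- tapply(sim, ulab, max)
    rank <- match(as.character(ulab), names(sort(csim, decreasing = TRUE)))
    labels[have, e] <- rank[match(seqs, uniq)]
    counts[e] <- length(unique(ulab))
  }
  n_loci <- max(1L, max(counts))
  chim <- character(0)
  multi <- which(counts >= 2L)
  if (length(multi)) {
    for (i in seq_along(tigs)) {
      l <- labels[i, multi]
      l <- l[!is.na(l)]
      if (length(unique(l)) >= 2L) chim <- c(chim, names(tigs)[i])
    }
  }
  if (n_loci == 1L) chim <- character(0)
  structure(list(isogroup_id = isogroup$isogroup_id %||% "isogroup",
                 n_loci = n_loci, exon_variant_counts = counts,
                 chimeric_isotigs = chim, labels = labels),
            class = "locus_inference")
}

#' @export
print.locus_inference <- function(x, ...) {
  cat("Locus inference for", x$isogroup_id, ": n_loci =", x$n_loci,
      ";", length(x$chimeric_isotigs), "chimeric isotig(s)\n")
  print(x$exon_variant_counts)
  invisible(x)
}

#' Isogroup size summary
#'
#' Counts of isogroups strictly exceeding each size threshold, plus the
#' mean number of isotigs per isogroup.
#'
#' @param groups Either a data frame with columns `isotig_id` and
#'   `isogroup_id`, or a list of isogroups each with an `isotigs` element.
#' @param thresholds Integer thresholds (strict `>`).
#' @return List with `counts` (named by threshold), `mean_isotigs` and
#'   `n_isogroups` (`mean_isotigs` is `NA` for empty input).
#' @export
isogroup_size_summary <- function(groups, thresholds = c(10L, 45L, 100L)) {
  sizes <- if (is.data.frame(groups)) {
    if (nrow(groups) == 0) integer(0)
    else as.integer(table(groups$isogroup_id))
  } else vapply(groups, function(g) length(g$isotigs), 0L)
  counts <- vapply(thresholds, function(t) sum(sizes > t), 0L)
  list(counts = setNames(counts, paste0(">", thresholds)),
       mean_isotigs = if (length(sizes)) sum(sizes) / length(sizes)
                      else NA_real_,
       n_isogroups = length(sizes))
}
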