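# GeneModel: a gene's genomic sequence with ordered exon/intron intervals.
# Exons are 0-based half-open intervals on the genomic sequence, plus
# strand only; introns are the gaps between consecutive exons; the mature
# mRNA is the concatenation of the exons.

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param genomic_seq Genomic DNA sequence (character).
#' @param exons Two-column matrix of 0-based half-open \[start, end)
#'   exon intervals, non-overlapping and sorted; each exon length >= 1 and
#'   each intron (gap between consecutive exons) length >= 1.
#' @return A `gene_model` object.
#' @export
gene_model <- function(gene_id, genomic_seq, exons) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  stopifnot(nrow(exons) >= 1,
            all(exons[, "end"] > exons[, "start"]),
            all(exons[, "start"] >= 0),
            all(exons[, "end"] <= nchar(genomic_seq)))
  if (nrow(exons) > 1) {
    gaps <- exons[-1, "start"] - exons[-nrow(exons), "end"]
    stopifnot(all(gaps >= 1))
  }
  structure(list(gene_id = gene_id, genomic_seq = toupper(genomic_seq),
                 exons = exons, strand = "+"),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene model", x$gene_id, ":", nchar(x$genomic_seq), "nt genomic,",
      nrow(x$exons), "exon(s),", max(0L, nrow(x$exons) - 1L),
      "intron(s)\n")
  invisible(x)
}

#' Mature mRNA of a gene model (concatenated exons)
#'
#' @param model A `gene_model`.
#' @return Character string.
#' @export
mature_mrna <- function(model) {
  paste(substring(model$genomic_seq, model$exons[, "start"] + 1L,
                  model$exons[, "end"]), collapse = "")
}

#' Intron intervals of a gene model
#'
#' @param model A `gene_model`.
#' @return Two-column matrix of 0-based half-open intron intervals (zero
#'   rows for single-exon genes).
#' @export
model_introns <- function(model) {
  ne <- nrow(model$exons)
  if (ne < 2)
    return(matrix(integer(0), 0, 2,
                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = model$exons[-ne, "end"], end = model$exons[-1, "start"])
}

# Ordered feature table: exon1, intron1, exon2, ... with genomic intervals.
feature_table <- function(model) {
  ex <- model$exons
  ne <- nrow(ex)
  feats <- data.frame(kind = "exon", index = seq_len(ne),
                      start = ex[, "start"], end = ex[, "end"])
  if (ne > 1) {
    int <- model_introns(model)
    feats <- rbind(feats,
                   data.frame(kind = "intron", index = seq_len(ne - 1L),
                              start = int[, "start"], end = int[, "end"]))
  }
  feats <- feats[order(feats$start), , drop = FALSE]
  feats$feature <- paste0(feats$kind, feats$index)
  rownames(feats) <- NULL
  feats
}

#' Write gene models as GFF3 + genomic FASTA
#'
#' One pseudo-chromosome per gene (named by gene id); GFF3 uses 1-based
#' inclusive coordinates with gene and exon features; FASTA is wrapped at
#' 80 columns.
#'
#' @param models List of `gene_model` objects.
#' @param gff3_path,fasta_path Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_gene_models <- function(models, gff3_path, fasta_path) {
  feats <- do.call(rbind, lapply(models, function(m) {
    ex <- m$exons
    rbind(data.frame(seq = m$gene_id, start = 1L,
                     end = nchar(m$genomic_seq), type = "gene",
                     id = m$gene_id, parent = NA_character_),
          data.frame(seq = m$gene_id, start = ex[, "start"] + 1L,
                     end = ex[, "end"], type = "exon",
                     id = paste0(m$gene_id, ".exon",
                                 seq_len(nrow(ex))),
                     parent = m$gene_id))
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = feats$seq,
    ranges = IRanges::IRanges(start = feats$start, end = feats$end),
    strand = "+", type = feats$type, ID = feats$id, Parent = feats$parent)
  rtracklayer::export(gr, gff3_path, format = "GFF3")
  seqs <- Biostrings::DNAStringSet(
    setNames(vapply(models, function(m) m$genomic_seq, ""),
             vapply(models, function(m) m$gene_id, "")))
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  invisible(list(gff3 = gff3_path, fasta = fasta_path))
}

#' Read gene models from GFF3 + genomic FASTA
#'
#' @param gff3_path,fasta_path Paths written by [write_gene_models()] (or
#'   equivalent gene/exon GFF3 with one sequence per gene).
#' @return List of `gene_model` objects.
#' @export
read_gene_models <- function(gff3_path, fasta_path) {
  gr <- rtracklayer::import(gff3_path, format = "GFF3")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ex <- gr[gr$type == "exon"]
  lapply(names(seqs), function(gid) {
    e <- ex[GenomicRanges::seqnames(ex) == gid]
    e <- e[order(GenomicRanges::start(e))]
    gene_model(gid, as.character(seqs[[gid]]),
               cbind(GenomicRanges::start(e) - 1L, GenomicRanges::end(e)))
  })
}

#' Protein encoded by a generated gene model
#'
#' Translates the principal coding region of the mature mRNA (available
#' for models from [generate_gene_models()], which record the CDS
#' interval); the trailing stop is dropped.
#'
#' @param model A `gene_model` with a `cds` interval.
#' @return Protein sequence (character).
#' @export
model_protein <- function(model) {
  if (is.null(model$cds)) stop("model carries no CDS interval")
  cds <- substr(mature_mrna(model), model$cds[1] + 1L, model$cds[2])
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  sub("\\*$", "", aa)
}

#' Assembly N50
#'
#' The smallest length L such that sequences of length >= L contain at
#' least half of the total assembled bases (ties resolved toward the
#' smaller length).
#'
#' @param lengths Integer vector of sequence lengths.
#' @return The N50 length (`NA` for empty input).
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) return(NA_real_)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}
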