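# Synthetic dual-species transcriptome generator. Defaults emulate the
# study system: two congeneric transcript sets at ~13% nucleotide
# divergence (median pairwise identity near 87%), a conserved subset
# evolving at one third of that rate, ~10% lineage-specific losses and ~5%
# duplications, isogroups whose isotigs are intron-retention variants, a
# mean of about 2.1 isotigs per isogroup, and short singleton fragments.
# One config seed determines every output byte.

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")
# stops in all three reading frames; embedded in introns so that any
# retained intron interrupts the open reading frame
.INTRON_STOP_BLOCK <- "TAAATAAATAA"

#' Configuration for the synthetic transcriptome generator
#'
#' @param n_genes Number of gene models.
#' @param exon_count_range,exon_len_range,intron_len_range Integer ranges
#'   (inclusive) sampled per gene.
#' @param divergence Per-site substitution probability between the two
#'   species, in \[0, 0.5).
#' @param conserved_fraction Fraction of genes evolved at `divergence / 3`.
#' @param loss_fraction Fraction of genes lost in species B.
#' @param duplication_fraction Fraction of genes duplicated in species B.
#' @param retention_prob Per-intron retention probability for splice
#'   isoforms.
#' @param n_isotigs_per_isogroup Target mean number of isotigs per
#'   isogroup (may be fractional; sizes are allocated so the realised mean
#'   matches the target to rounding).
#' @param singleton_fraction Fraction of transcripts emitted as short
#'   fragments.
#' @param seed Integer seed; fully determines all output.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_genes = 100L,
                              exon_count_range = c(3L, 9L),
                              exon_len_range = c(60L, 240L),
                              intron_len_range = c(50L, 200L),
                              divergence = 0.13,
                              conserved_fraction = 0.2,
                              loss_fraction = 0.1,
                              duplication_fraction = 0.05,
                              retention_prob = 0.5,
                              n_isotigs_per_isogroup = 2.1,
                              singleton_fraction = 0.15,
                              seed = 1L) {
  chk_range <- function(r, what) {
    if (length(r) != 2 || any(r < 1) || r[1] > r[2])
      stop("invalid ", what, ": min must be <= max and both positive")
    as.integer(r)
  }
  fr <- c(conserved_fraction, loss_fraction, duplication_fraction,
          retention_prob, singleton_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (conserved_fraction + loss_fraction + duplication_fraction > 1)
    stop("conserved + loss + duplication fractions must not exceed 1")
  if (divergence < 0 || divergence >= 0.5)
    stop("divergence must lie in [0, 0.5)")
  cfg <- list(n_genes = as.integer(n_genes),
              exon_count_range = chk_range(exon_count_range,
                                           "exon_count_range"),
              exon_len_range = chk_range(exon_len_range, "exon_len_range"),
              intron_len_range = chk_range(intron_len_range,
                                           "intron_len_range"),
              divergence = divergence,
              conserved_fraction = conserved_fraction,
              loss_fraction = loss_fraction,
              duplication_fraction = duplication_fraction,
              retention_prob = retention_prob,
              n_isotigs_per_isogroup = n_isotigs_per_isogroup,
              singleton_fraction = singleton_fraction,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

.rand_dna <- function(n) paste(sample(.BASES, n, replace = TRUE),
                               collapse = "")

.sample_range <- function(r, n = 1L) {
  if (r[1] == r[2]) rep.int(r[1], n) else sample(r[1]:r[2], n, replace = TRUE)
}

# short UTR free of ATG so the coding start is unambiguous
.rand_utr <- function(n) {
  repeat {
    s <- .rand_dna(n)
    if (!grepl("ATG", s, fixed = TRUE)) return(s)
  }
}

.NONSTOP_CODONS <- local({
  all64 <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0))
  sort(setdiff(all64, .STOPS))
})

# complete ATG..stop ORF lengths in all six frames (generator-internal
# validator, independent of find_longest_orf)
.complete_orf_lengths <- function(seq) {
  res <- integer(0)
  for (s in c(seq, revcomp(seq))) {
    n <- nchar(s)
    for (f in 1:3) {
      len <- ((n - f + 1L) %/% 3L) * 3L
      if (len < 3L) next
      cods <- substring(s, seq(f, f + len - 3L, 3L), seq(f + 2L, f + len - 1L, 3L))
      stops <- c(0L, which(cods %in% .STOPS))
      for (i in seq_len(length(stops) - 1L)) {
        seg <- (stops[i] + 1L):(stops[i + 1L] - 1L)
        if (!length(seg)) next
        m <- seg[match("ATG", cods[seg])]
        if (!is.na(m)) res <- c(res, 3L * (stops[i + 1L] - m + 1L))
      }
    }
  }
  res
}

# one mature mRNA of given length: 5' UTR + ATG + stop-free codons + stop +
# 3' UTR, resampled until the intended CDS is the unique longest complete
# ORF on either strand
.make_mature <- function(len) {
  if (len < 30L) return(list(seq = .rand_dna(len), cds = NULL))
  utr5 <- 9L
  utr3 <- 9L + (len - 21L) %% 3L
  ncod <- (len - utr5 - utr3) %/% 3L   # includes ATG and the stop
  for (attempt in 1:50) {
    cds <- paste0("ATG",
                  paste(sample(.NONSTOP_CODONS, ncod - 2L, replace = TRUE),
                        collapse = ""),
                  sample(.STOPS, 1L))
    seq <- paste0(.rand_utr(utr5), cds, .rand_utr(utr3))
    lens <- .complete_orf_lengths(seq)
    if (sum(lens == 3L * ncod) == 1L && max(lens) == 3L * ncod)
      return(list(seq = seq, cds = c(utr5, utr5 + 3L * ncod)))
  }
  stop("could not construct a mature mRNA with a unique principal ORF")
}

.make_intron <- function(len) {
  if (len < 15L) return(.rand_dna(len))
  pre <- (len - 15L) %/% 2L
  paste0("GT", .rand_dna(pre), .INTRON_STOP_BLOCK,
         .rand_dna(len - 15L - pre), "AG")
}

#' Generate seeded gene models
#'
#' Each gene has a sampled number of exons and exon/intron lengths; the
#' mature mRNA (concatenated exons) carries a complete ORF spanning most of
#' its length, and every intron embeds stop codons in all three frames so
#' that intron retention interrupts the reading frame.
#'
#' @param config A [simulation_config()].
#' @param outdir Optional directory; when given, `genome.fa` (80-column
#'   FASTA) and `models.gff3` (1-based inclusive) are written there.
#' @return List of `gene_model` objects (invisibly carries the output
#'   paths as an attribute when `outdir` is given).
#' @export
generate_gene_models <- function(config, outdir = NULL) {
  models <- with_op_seed(config$seed, "generate_gene_models", {
    lapply(seq_len(config$n_genes), function(i) {
      gid <- sprintf("g%04d", i)
      ne <- .sample_range(config$exon_count_range)
      exlens <- .sample_range(config$exon_len_range, ne)
      mm <- .make_mature(sum(exlens))
      pieces <- character(2L * ne - 1L)
      exons <- matrix(0L, ne, 2L, dimnames = list(NULL, c("start", "end")))
      pos <- 0L; off <- 0L
      for (e in seq_len(ne)) {
        pieces[2L * e - 1L] <- substr(mm$seq, off + 1L, off + exlens[e])
        exons[e, ] <- c(pos, pos + exlens[e])
        pos <- pos + exlens[e]
        off <- off + exlens[e]
        if (e < ne) {
          il <- .sample_range(config$intron_len_range)
          pieces[2L * e] <- .make_intron(il)
          pos <- pos + il
        }
      }
      m <- gene_model(gid, paste(pieces, collapse = ""), exons)
      m$cds <- mm$cds
      m
    })
  })
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- write_gene_models(models, file.path(outdir, "models.gff3"),
                               file.path(outdir, "genome.fa"))
    attr(models, "paths") <- paths
  }
  models
}
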