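# Orchestration: the read-quality filter, the end-to-end pipeline over a
# simulated dataset, per-stage TSV outputs with JSON provenance records,
# and the human-readable summary report.

#' Quality filter for sequencing reads
#'
#' A read passes iff its (mean, by default) phred score is at least
#' `min_phred`, its length at least `min_len`, it contains at most
#' `max_ambig` non-ACGT bases, and its longest single-base run is at most
#' `max_homopolymer`. The rejection log records the first failing rule per
#' read, checked in that order.
#'
#' @param reads Path to a FASTQ file or a
#'   `Biostrings::QualityScaledDNAStringSet`.
#' @param min_phred Minimum phred score (mean or minimum per
#'   `phred_mode`).
#' @param min_len Minimum read length.
#' @param max_ambig Maximum number of non-ACGT bases.
#' @param max_homopolymer Maximum single-base run length.
#' @param phred_mode `"mean"` (default) or `"min"`.
#' @param fasta_out Optional path; passing reads are written there as
#'   FASTA.
#' @return List with `pass` (named character vector of passing reads) and
#'   `log` (data frame read_id / rule for rejected reads).
#' @export
filter_reads <- function(reads, min_phred = 25, min_len = 100,
                         max_ambig = 0, max_homopolymer = 8,
                         phred_mode = c("mean", "min"),
                         fasta_out = NULL) {
  phred_mode <- match.arg(phred_mode)
  if (is.character(reads)) {
    reads <- tryCatch(
      suppressWarnings(Biostrings::readQualityScaledDNAStringSet(reads)),
      error = function(e) stop("malformed FASTQ: ", conditionMessage(e)))
  }
  ids <- names(reads) %||% sprintf("read%04d", seq_along(reads))
  seqs <- suppressWarnings(as.character(reads))
  quals <- as(Biostrings::quality(reads), "IntegerList")
  agg <- if (phred_mode == "mean") mean else min
  rule <- vapply(seq_along(seqs), function(i) {
    s <- seqs[i]
    if (agg(quals[[i]]) < min_phred) return("phred")
    if (nchar(s) < min_len) return("length")
    nb <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                      letters = "ACGT", OR = 0)
    if (nchar(s) - sum(nb) > max_ambig) return("ambiguity")
    if (max(rle(strsplit(s, "", fixed = TRUE)[[1]])$lengths) >
        max_homopolymer) return("homopolymer")
    "pass"
  }, "")
  pass <- setNames(seqs[rule == "pass"], ids[rule == "pass"])
  if (!is.null(fasta_out))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(pass), fasta_out,
                                width = 80L)
  list(pass = pass,
       log = data.frame(read_id = ids[rule != "pass"],
                        rule = rule[rule != "pass"],
                        stringsAsFactors = FALSE))
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.provenance <- function(outdir, stage, params, inputs = character(0),
                        seed = NULL) {
  rec <- list(stage = stage, seed = seed, parameters = params,
              inputs = as.list(tools::md5sum(inputs)),
              package_version =
                as.character(utils::packageVersion("orthosplice")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(rec, file.path(outdir,
                                      paste0(stage, ".provenance.json")),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
}

.stage_done <- function(outdir, files) {
  all(file.exists(file.path(outdir, files)))
}

#' Run the comparative-transcriptomics pipeline on a simulated dataset
#'
#' Executes the requested stages in dependency order over a seeded
#' simulation: `simulate` (gene models, species pair, splice isoforms,
#' singleton fragments, truth tables), `search` (both directions),
#' `rbh`, `histogram`, `conserved`, `splice`, `kaks`, and `report`. Each
#' stage writes TSV outputs plus a JSON provenance record to `outdir`;
#' completed stages are skipped on re-runs unless `force` is set.
#'
#' @param config List with optional entries `simulation` (arguments to
#'   [simulation_config()]), `search` (arguments to [search_params()]),
#'   `conserved_threshold` (default 93), and `stages` (default all).
#' @param outdir Output directory.
#' @param force Re-run completed stages.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config = list(), outdir, force = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  all_stages <- c("simulate", "search", "rbh", "histogram", "conserved",
                  "splice", "kaks", "report")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage: ", bad[1])
  sim_cfg <- do.call(simulation_config, config$simulation %||% list())
  params <- do.call(search_params, config$search %||% list())
  seed <- sim_cfg$seed
  p <- function(f) file.path(outdir, f)

  if ("simulate" %in% stages &&
      (force || !.stage_done(outdir, c("species_a.fa", "species_b.fa",
                                       "truth_orthologs.tsv")))) {
    models <- generate_gene_models(sim_cfg, outdir = outdir)
    pair <- evolve_species_pair(models, sim_cfg)
    a_tx <- fragment_transcripts(pair$species_a, sim_cfg)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(a_tx), p("species_a.fa"), width = 80L)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(pair$species_b), p("species_b.fa"),
      width = 80L)
    .write_tsv(data.frame(gene_id = names(pair$truth$ortholog_truth),
                          ortholog = unname(pair$truth$ortholog_truth),
                          conserved = names(pair$truth$ortholog_truth) %in%
                            pair$truth$conserved_genes,
                          duplicated = names(pair$truth$ortholog_truth) %in%
                            pair$truth$duplication_truth),
               p("truth_orthologs.tsv"))
    .write_tsv(attr(a_tx, "singleton_map"), p("truth_singletons.tsv"))
    .provenance(outdir, "simulate", unclass(sim_cfg), seed = seed)
  }

  if ("search" %in% stages &&
      (force || !.stage_done(outdir, c("hits_ab.tsv", "hits_ba.tsv")))) {
    a_tx <- .read_fasta_chr(p("species_a.fa"))
    b_tx <- .read_fasta_chr(p("species_b.fa"))
    idx_b <- build_seed_index(b_tx, params)
    idx_a <- build_seed_index(a_tx, params)
    write_hsp_tsv(search_nucleotide(a_tx, idx_b, params), p("hits_ab.tsv"))
    write_hsp_tsv(search_nucleotide(b_tx, idx_a, params), p("hits_ba.tsv"))
    .provenance(outdir, "search", unclass(params),
                inputs = c(p("species_a.fa"), p("species_b.fa")),
                seed = seed)
  }

  if ("rbh" %in% stages && (force || !.stage_done(outdir, "pairs.tsv"))) {
    pairs <- reciprocal_best_hits(read_hsp_tsv(p("hits_ab.tsv")),
                                  read_hsp_tsv(p("hits_ba.tsv")))
    write_pairs_tsv(pairs, p("pairs.tsv"))
    .provenance(outdir, "rbh", list(),
                inputs = c(p("hits_ab.tsv"), p("hits_ba.tsv")),
                seed = seed)
  }

  if ("histogram" %in% stages &&
      (force || !.stage_done(outdir, "histogram.tsv"))) {
    pairs <- .read_pairs(p("pairs.tsv"))
    write_histogram_tsv(similarity_histogram(pairs), p("histogram.tsv"))
    .provenance(outdir, "histogram", list(), inputs = p("pairs.tsv"),
                seed = seed)
  }

  if ("conserved" %in% stages &&
      (force || !.stage_done(outdir, "conserved.tsv"))) {
    thr <- config$conserved_threshold %||% 93
    pairs <- .read_pairs(p("pairs.tsv"))
    .write_tsv(as.data.frame(select_conserved(pairs, thr)),
               p("conserved.tsv"))
    .provenance(outdir, "conserved", list(threshold = thr),
                inputs = p("pairs.tsv"), seed = seed)
  }

  if ("splice" %in% stages &&
      (force || !.stage_done(outdir, "splice_calls.tsv"))) {
    models <- read_gene_models(p("models.gff3"), p("genome.fa"))
    model <- Filter(function(m) nrow(m$exons) >= 2, models)[[1]]
    iso <- generate_splice_isoforms(model, sim_cfg,
                                    n_isotigs = config$n_splice_isotigs %||%
                                      12L)
    calls <- lapply(names(iso$sequences), function(id) {
      a <- map_transcript_to_model(iso$sequences[[id]], model, params,
                                   isotig_id = id)
      call_intron_retention(a, model)
    })
    .write_tsv(data.frame(
      isotig_id = vapply(calls, `[[`, "", "isotig_id"),
      retained = vapply(calls, function(x)
        paste(x$retained_introns, collapse = ","), ""),
      complete_orf = vapply(calls, `[[`, TRUE, "complete_orf")),
      p("splice_calls.tsv"))
    .write_tsv(iso$splice_truth, p("truth_splice.tsv"))
    .provenance(outdir, "splice", list(gene = model$gene_id),
                inputs = c(p("models.gff3"), p("genome.fa")), seed = seed)
  }

  if ("kaks" %in% stages && (force || !.stage_done(outdir, "kaks.tsv"))) {
    cp <- simulate_codon_pair(config$kaks_codons %||% 500L,
                              config$kaks_omega %||% 0.4,
                              config$kaks_t %||% 0.3, seed = seed)
    res <- kaks_ng86(cp$a, cp$b)
    .write_tsv(data.frame(S = res$S, N = res$N, Sd = res$Sd, Nd = res$Nd,
                          ds = res$ds, dn = res$dn, ratio = res$ratio,
                          codons_used = res$codons_used,
                          omega_truth = cp$omega),
               p("kaks.tsv"))
    .provenance(outdir, "kaks", list(omega = cp$omega, t = cp$t),
                seed = seed)
  }

  if ("report" %in% stages && (force || !file.exists(p("report.txt"))))
    write_report(outdir)
  invisible(outdir)
}

.read_fasta_chr <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

.read_pairs <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  class(df) <- c("ortholog_pairs", "data.frame")
  df
}

#' Write the human-readable summary report for a pipeline run
#'
#' Summarizes transcriptome statistics (transcript counts, N50), ortholog
#' counts with median similarity and the occupied histogram bins, the
#' conserved subset, splice calls and the Ka/Ks stage from the TSV outputs
#' present in `outdir`.
#'
#' @param outdir A [run_pipeline()] output directory with at least one
#'   stage output.
#' @return The report path, invisibly.
#' @export
write_report <- function(outdir) {
  p <- function(f) file.path(outdir, f)
  lines <- c("Comparative transcriptomics pipeline report",
             strrep("=", 44))
  found <- FALSE
  if (file.exists(p("species_a.fa"))) {
    found <- TRUE
    a <- .read_fasta_chr(p("species_a.fa"))
    lens <- nchar(a)
    lines <- c(lines, "",
               sprintf("Species A transcripts: %d (%d singletons)",
                       length(a), sum(grepl("singleton", names(a)))),
               sprintf("  mean length %.0f nt, N50 %d nt", mean(lens),
                       n50(lens)))
  }
  if (file.exists(p("pairs.tsv"))) {
    found <- TRUE
    pairs <- .read_pairs(p("pairs.tsv"))
    lines <- c(lines, "",
               sprintf("Putative ortholog pairs (RBH): %d", nrow(pairs)),
               sprintf("  median similarity %.1f%%, mean %.1f%%",
                       median(pairs$similarity), mean(pairs$similarity)),
               sprintf("  pairs with isotigs: %d, with singletons: %d",
                       sum(pairs$a_class == "isotig"),
                       sum(pairs$a_class == "singleton")))
    h <- similarity_histogram(pairs)
    occ <- h$counts[h$counts > 0]
    lines <- c(lines, "  similarity histogram (bin lower edge: count):",
               paste("   ", paste(sprintf("%s%%:%d", names(occ), occ),
                                  collapse = " ")))
  }
  if (file.exists(p("conserved.tsv"))) {
    found <- TRUE
    cons <- read.table(p("conserved.tsv"), sep = "\t", header = TRUE)
    lines <- c(lines, sprintf("Conserved subset (isotig pairs): %d",
                              nrow(cons)))
  }
  if (file.exists(p("splice_calls.tsv"))) {
    found <- TRUE
    sc <- read.table(p("splice_calls.tsv"), sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    nret <- vapply(strsplit(as.character(sc$retained), ","),
                   function(x) length(x[nzchar(x)]), 0L)
    lines <- c(lines, "",
               sprintf("Splice calls: %d isotigs, mean %.2f retained introns",
                       nrow(sc), mean(nret)),
               sprintf("  complete ORF: %d isotig(s)",
                       sum(sc$complete_orf)))
  }
  if (file.exists(p("kaks.tsv"))) {
    found <- TRUE
    kk <- read.table(p("kaks.tsv"), sep = "\t", header = TRUE)
    lines <- c(lines, "",
               sprintf("Ka/Ks (NG86): dn/ds = %.3f over %d codons (truth %.2f)",
                       kk$ratio, kk$codons_used, kk$omega_truth))
  }
  if (!found) stop("no stage output present in ", outdir)
  writeLines(lines, p("report.txt"))
  invisible(p("report.txt"))
}
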