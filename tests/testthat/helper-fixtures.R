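# Shared fixture builders. Everything is generated in code under fixed
# seeds; heavier fixtures are memoised so several test files can reuse
# them within one run.

.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# mutate a sequence at a fixed per-site rate (independent of the package's
# internal mutation helper)
mutate_dna <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# the packaged 100-gene two-species fixture: divergence 0.13, 10% loss,
# 5% duplication, 20% conserved subset, fixed seed
rbh_fixture <- function() {
  memo_fixture("rbh100", function() {
    cfg <- simulation_config(n_genes = 100, seed = 20)
    models <- generate_gene_models(cfg)
    pair <- evolve_species_pair(models, cfg)
    a_tx <- fragment_transcripts(pair$species_a, cfg)
    params <- search_params()
    hits_ab <- search_nucleotide(a_tx, build_seed_index(pair$species_b,
                                                        params), params)
    hits_ba <- search_nucleotide(pair$species_b,
                                 build_seed_index(a_tx, params), params)
    pairs <- reciprocal_best_hits(hits_ab, hits_ba)
    list(cfg = cfg, models = models, pair = pair, a_tx = a_tx,
         hits_ab = hits_ab, hits_ba = hits_ba, pairs = pairs)
  })
}

# map RBH predictions back to truth gene ids (fragments keep their source
# gene id behind the singleton_ prefix)
rbh_truth_stats <- function(fx) {
  truth <- fx$pair$truth$ortholog_truth
  truth <- truth[truth != "ABSENT"]
  pred_a <- sub("^singleton_", "", fx$pairs$id_a)
  tp <- sum(!is.na(truth[pred_a]) & truth[pred_a] == fx$pairs$id_b)
  list(tp = tp, precision = tp / nrow(fx$pairs),
       recall = tp / length(truth))
}

# one multi-intron gene model under a fixed seed
intron_model <- function(n_exons = 9, seed = 11) {
  cfg <- simulation_config(n_genes = 1,
                           exon_count_range = c(n_exons, n_exons),
                           seed = seed)
  generate_gene_models(cfg)[[1]]
}

# independent brute-force NG86 pathway enumerator (recursive; shares no
# code with the package implementation)
oracle_pair <- function(c1, c2) {
  GC <- Biostrings::GENETIC_CODE
  stops <- c("TAA", "TAG", "TGA")
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  paths <- list()
  walk <- function(cur, left, s, n) {
    if (!length(left)) {
      paths[[length(paths) + 1]] <<- c(s, n)
      return()
    }
    for (p in left) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% stops) next
      walk(nxt, setdiff(left, p), s + (GC[[nxt]] == GC[[cur]]),
           n + (GC[[nxt]] != GC[[cur]]))
    }
  }
  walk(c1, pos, 0, 0)
  if (!length(paths)) return(c(NA_real_, NA_real_))
  colMeans(do.call(rbind, paths))
}

write_fastq <- function(path, records) {
  writeLines(unlist(lapply(records, function(r)
    c(paste0("@", r$id), r$seq, "+",
      paste(rep(r$q, nchar(r$seq)), collapse = "")))), path)
}
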