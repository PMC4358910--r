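# Evolution of a species pair from shared gene models, splice-isoform and
# singleton-fragment generation, and codon-pair simulation with known
# omega. Mutation model: per-site uniform substitution to one of the three
# alternative bases, no indels (so the expected pairwise identity of a
# non-conserved ortholog pair is 1 - divergence).

.mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate & ch %in% .BASES)
  if (length(hit)) {
    cur <- match(ch[hit], .BASES)
    ch[hit] <- .BASES[1L + (cur - 1L +
                            sample.int(3L, length(hit),
                                       replace = TRUE)) %% 4L]
  }
  paste(ch, collapse = "")
}

#' Evolve a species pair from shared gene models
#'
#' Species A transcripts are the mature mRNAs of the models. Species B
#' transcripts are per-site mutated copies at rate `divergence` (a
#' conserved subset at `divergence / 3`), minus lost genes, plus extra
#' diverged copies (2 x `divergence` on top of the ortholog copy) for
#' duplicated genes. The truth set records the ortholog map (or ABSENT),
#' the duplicated genes and the conserved subset.
#'
#' @param models List of `gene_model` objects.
#' @param config A [simulation_config()].
#' @return List with `species_a`, `species_b` (named character vectors)
#'   and `truth` (list with `ortholog_truth`, `duplication_truth`,
#'   `conserved_genes`).
#' @export
evolve_species_pair <- function(models, config) {
  stopifnot(config$divergence < 0.5)
  gids <- vapply(models, function(m) m$gene_id, "")
  a <- setNames(vapply(models, mature_mrna, ""), gids)
  with_op_seed(config$seed, "evolve_species_pair", {
    n <- length(models)
    n_cons <- round(config$conserved_fraction * n)
    n_loss <- round(config$loss_fraction * n)
    n_dup <- round(config$duplication_fraction * n)
    perm <- sample.int(n)
    conserved <- gids[perm[seq_len(n_cons)]]
    lost <- gids[perm[n_cons + seq_len(n_loss)]]
    dup <- gids[perm[n_cons + n_loss + seq_len(n_dup)]]
    b <- list()
    ortho <- setNames(rep("ABSENT", n), gids)
    for (g in gids) {
      if (g %in% lost) next
      rate <- if (g %in% conserved) config$divergence / 3
              else config$divergence
      bid <- paste0(g, "_B")
      b[[bid]] <- .mutate_seq(a[[g]], rate)
      ortho[g] <- bid
      if (g %in% dup)
        b[[paste0(g, "_Bdup")]] <- .mutate_seq(b[[bid]],
                                               2 * config$divergence)
    }
    list(species_a = a, species_b = unlist(b),
         truth = list(ortholog_truth = ortho,
                      duplication_truth = dup,
                      conserved_genes = conserved))
  })
}

#' Generate intron-retention splice isoforms for one gene model
#'
#' Each isotig is the concatenation of all exons with every intron
#' independently retained with probability `retention_prob`; the first
#' isotig is forced to zero retained introns (the correctly spliced
#' transcript). All isotigs share one isogroup id (the gene id).
#'
#' @param model A `gene_model`.
#' @param config A [simulation_config()].
#' @param n_isotigs Number of isotigs to emit (default: the config target
#'   rounded, at least 2).
#' @return List with `sequences` (named character vector), `isogroup`
#'   (data frame isotig_id / isogroup_id), `splice_truth` (data frame
#'   isotig_id / gene_id / retained, comma-separated 1-based intron
#'   indices) and `warnings` (character).
#' @export
generate_splice_isoforms <- function(model, config, n_isotigs = NULL) {
  n_isotigs <- n_isotigs %||% max(2L, round(config$n_isotigs_per_isogroup))
  feats <- feature_table(model)
  n_int <- sum(feats$kind == "intron")
  warnings <- character(0)
  if (n_int == 0L && config$retention_prob > 0)
    warnings <- paste0("model ", model$gene_id,
                       " has no introns; isotigs are identical")
  with_op_seed(config$seed, paste0("splice_", model$gene_id), {
    iso <- lapply(seq_len(n_isotigs), function(i) {
      retained <- if (i == 1L || n_int == 0L) integer(0)
                  else which(runif(n_int) < config$retention_prob)
      keep <- feats$kind == "exon" |
        (feats$kind == "intron" & feats$index %in% retained)
      seq <- paste(substring(model$genomic_seq, feats$start[keep] + 1L,
                             feats$end[keep]), collapse = "")
      list(seq = seq, retained = retained)
    })
    ids <- sprintf("%s_iso%02d", model$gene_id, seq_len(n_isotigs))
    list(sequences = setNames(vapply(iso, `[[`, "", "seq"), ids),
         isogroup = data.frame(isotig_id = ids,
                               isogroup_id = model$gene_id,
                               stringsAsFactors = FALSE),
         splice_truth = data.frame(
           isotig_id = ids, gene_id = model$gene_id,
           retained = vapply(iso, function(x)
             paste(x$retained, collapse = ","), ""),
           stringsAsFactors = FALSE),
         warnings = warnings)
  })
}

#' Allocate isogroup sizes for a target mean isotig count
#'
#' Distributes `round(mean_size * n_groups)` isotigs over `n_groups`
#' isogroups (each at least one isotig): every group receives the base
#' count and a seeded random subset receives one extra, so the realised
#' mean equals the target up to rounding of the total.
#'
#' @param n_groups Number of isogroups.
#' @param mean_size Target mean isotigs per isogroup (>= 1, may be
#'   fractional).
#' @param seed Integer seed.
#' @return Integer vector of group sizes.
#' @export
allocate_isogroup_sizes <- function(n_groups, mean_size, seed = 1L) {
  stopifnot(n_groups >= 1, mean_size >= 1)
  total <- max(n_groups, round(mean_size * n_groups))
  base <- total %/% n_groups
  extra <- total - base * n_groups
  with_op_seed(seed, "allocate_isogroup_sizes", {
    sizes <- rep.int(base, n_groups)
    if (extra > 0) {
      up <- sample.int(n_groups, extra)
      sizes[up] <- sizes[up] + 1L
    }
    sizes
  })
}

#' Replace a fraction of transcripts by singleton fragments
#'
#' A seeded subset of the transcripts is replaced by one uniform-random
#' contiguous substring of 40-80% of the source length, never shorter than
#' 100 nt when the source allows it. Fragment ids are prefixed
#' `singleton_`.
#'
#' @param transcripts Named character vector.
#' @param config A [simulation_config()].
#' @return Named character vector with the selected entries replaced and
#'   renamed; attribute `singleton_map` records original id, fragment id,
#'   0-based start and length.
#' @export
fragment_transcripts <- function(transcripts, config) {
  n_frag <- round(config$singleton_fraction * length(transcripts))
  if (n_frag == 0L) {
    attr(transcripts, "singleton_map") <-
      data.frame(original_id = character(0), singleton_id = character(0),
                 start = integer(0), length = integer(0))
    return(transcripts)
  }
  with_op_seed(config$seed, "fragment_transcripts", {
    pick <- sample(names(transcripts), n_frag)
    map <- data.frame(original_id = pick,
                      singleton_id = paste0("singleton_", pick),
                      start = 0L, length = 0L, stringsAsFactors = FALSE)
    for (i in seq_len(n_frag)) {
      src <- transcripts[[pick[i]]]
      L <- nchar(src)
      flen <- round(runif(1, 0.4, 0.8) * L)
      flen <- min(L, max(flen, min(100L, L)))
      start <- sample.int(L - flen + 1L, 1L) - 1L
      transcripts[[pick[i]]] <- substr(src, start + 1L, start + flen)
      map$start[i] <- start; map$length[i] <- flen
    }
    names(transcripts)[match(pick, names(transcripts))] <-
      paste0("singleton_", pick)
    attr(transcripts, "singleton_map") <- map
    transcripts
  })
}

#' Simulate an in-frame coding-sequence pair with known omega
#'
#' Starting from a random stop-free codon sequence, Poisson numbers of
#' synonymous (`t * S` expected) and nonsynonymous (`omega * t * N`
#' expected) single-nucleotide substitutions are applied at uniformly
#' chosen eligible positions; proposals creating stop codons are rejected.
#' `S` and `N` are the NG86 site counts of the ancestral sequence, so the
#' realised synonymous divergence is about `t` and dN/dS about `omega` in
#' expectation.
#'
#' @param n_codons Number of codons.
#' @param omega Simulated dN/dS ratio (>= 0).
#' @param t Expected synonymous substitutions per synonymous site (>= 0).
#' @param seed Integer seed.
#' @return List with sequences `a` and `b`, the simulated `omega` and `t`,
#'   and the realised event counts `n_syn`, `n_non`.
#' @export
simulate_codon_pair <- function(n_codons, omega, t, seed = 1L) {
  if (omega < 0 || t < 0) stop("omega and t must be non-negative")
  with_op_seed(seed, "simulate_codon_pair", {
    cods <- sample(.NONSTOP_CODONS, n_codons, replace = TRUE)
    a <- cods
    sites <- ng86_sites(cods)
    S <- sum(sites[, "s_sites"]); N <- sum(sites[, "n_sites"])
    n_syn <- rpois(1L, t * S)
    n_non <- rpois(1L, omega * t * N)
    events <- sample(c(rep("s", n_syn), rep("n", n_non)))
    for (ev in events) {
      for (try in 1:10000) {
        ci <- sample.int(n_codons, 1L)
        pos <- sample.int(3L, 1L)
        old <- cods[ci]
        base <- substr(old, pos, pos)
        alt <- sample(setdiff(.BASES, base), 1L)
        new <- old
        substr(new, pos, pos) <- alt
        if (new %in% .STOPS) next
        syn <- .codon_aa(new) == .codon_aa(old)
        if ((ev == "s") == syn) { cods[ci] <- new; break }
      }
    }
    list(a = paste(a, collapse = ""), b = paste(cods, collapse = ""),
         omega = omega, t = t, n_syn = n_syn, n_non = n_non)
  })
}
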