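# Synthetic dual-species generator: gene-model invariants, determinism,
# divergence calibration, losses/duplications, splice isoforms, fragments
# and the codon-pair simulator.

test_that("generated gene models satisfy the exon/intron invariants", {
  cfg <- simulation_config(n_genes = 10, seed = 4)
  models <- generate_gene_models(cfg)
  expect_length(models, 10)
  for (m in models) {
    ex <- m$exons
    expect_true(all(ex[, "end"] > ex[, "start"]))
    if (nrow(ex) > 1)
      expect_true(all(ex[-1, "start"] - ex[-nrow(ex), "end"] >= 1))
    expect_identical(nchar(mature_mrna(m)), sum(ex[, "end"] - ex[, "start"]))
    expect_true(nrow(ex) >= cfg$exon_count_range[1] &&
                  nrow(ex) <= cfg$exon_count_range[2])
  }
})

test_that("a single-exon gene has no introns and mature mRNA equals genome", {
  cfg <- simulation_config(n_genes = 1, exon_count_range = c(1, 1),
                           seed = 2)
  m <- generate_gene_models(cfg)[[1]]
  expect_identical(nrow(model_introns(m)), 0L)
  expect_identical(mature_mrna(m), m$genomic_seq)
})

test_that("a 16-exon gene carries 15 introns", {
  cfg <- simulation_config(n_genes = 2, exon_count_range = c(16, 16),
                           seed = 6)
  for (m in generate_gene_models(cfg))
    expect_identical(nrow(model_introns(m)), 15L)
})

test_that("the same seed reproduces byte-identical FASTA and GFF3", {
  cfg <- simulation_config(n_genes = 12, seed = 7)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  generate_gene_models(cfg, outdir = d1)
  generate_gene_models(cfg, outdir = d2)
  for (f in c("genome.fa", "models.gff3"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("invalid ranges and fractions are rejected", {
  expect_error(simulation_config(exon_count_range = c(5, 2)), "invalid")
  expect_error(simulation_config(divergence = 0.6), "divergence")
  expect_error(simulation_config(conserved_fraction = 0.6,
                                 loss_fraction = 0.3,
                                 duplication_fraction = 0.2), "exceed")
})

test_that("zero divergence gives identical species and an identity truth map", {
  cfg <- simulation_config(n_genes = 8, divergence = 0,
                           conserved_fraction = 0, loss_fraction = 0,
                           duplication_fraction = 0, seed = 5)
  pair <- evolve_species_pair(generate_gene_models(cfg), cfg)
  expect_identical(unname(pair$species_b),
                   unname(pair$species_a))
  expect_true(all(pair$truth$ortholog_truth ==
                    paste0(names(pair$truth$ortholog_truth), "_B")))
})

test_that("loss fraction forces the exact number of ABSENT genes", {
  cfg <- simulation_config(n_genes = 100, loss_fraction = 0.1, seed = 13)
  pair <- evolve_species_pair(generate_gene_models(cfg), cfg)
  expect_identical(sum(pair$truth$ortholog_truth == "ABSENT"), 10L)
  lost <- names(pair$truth$ortholog_truth)[
    pair$truth$ortholog_truth == "ABSENT"]
  expect_false(any(paste0(lost, "_B") %in% names(pair$species_b)))
})

test_that("pairwise divergence of non-conserved orthologs matches the rate", {
  cfg <- simulation_config(n_genes = 30, divergence = 0.13,
                           conserved_fraction = 0, loss_fraction = 0,
                           duplication_fraction = 0, seed = 21)
  pair <- evolve_species_pair(generate_gene_models(cfg), cfg)
  diffs <- vapply(names(pair$species_a), function(g) {
    a <- strsplit(pair$species_a[[g]], "")[[1]]
    b <- strsplit(pair$species_b[[paste0(g, "_B")]], "")[[1]]
    mean(a != b)
  }, 0)
  n_sites <- sum(nchar(pair$species_a))
  se <- sqrt(0.13 * 0.87 / n_sites)
  expect_lt(abs(mean(diffs) - 0.13), 4 * se)
})

test_that("splice isoforms: retention 0 and 1 behave as forced", {
  m <- intron_model(9, seed = 11)   # 8 introns
  cfg0 <- simulation_config(retention_prob = 0, seed = 1)
  iso0 <- generate_splice_isoforms(m, cfg0, n_isotigs = 5)
  expect_true(all(iso0$sequences == mature_mrna(m)))
  cfg1 <- simulation_config(retention_prob = 1, seed = 1)
  iso1 <- generate_splice_isoforms(m, cfg1, n_isotigs = 5)
  expect_identical(iso1$splice_truth$retained[1], "")
  expect_true(all(iso1$splice_truth$retained[-1] ==
                    paste(1:8, collapse = ",")))
  expect_true(all(iso1$sequences[-1] == m$genomic_seq))
})

test_that("splice isoform generation is seed-deterministic", {
  m <- intron_model(6, seed = 3)
  cfg <- simulation_config(retention_prob = 0.5, seed = 19)
  i1 <- generate_splice_isoforms(m, cfg, n_isotigs = 16)
  i2 <- generate_splice_isoforms(m, cfg, n_isotigs = 16)
  expect_identical(i1$splice_truth, i2$splice_truth)
  expect_identical(i1$sequences, i2$sequences)
})

test_that("zero-intron model with positive retention yields a warning record", {
  cfg <- simulation_config(n_genes = 1, exon_count_range = c(1, 1),
                           retention_prob = 0.5, seed = 2)
  m <- generate_gene_models(cfg)[[1]]
  iso <- generate_splice_isoforms(m, cfg, n_isotigs = 3)
  expect_length(iso$warnings, 1)
  expect_true(all(iso$sequences == mature_mrna(m)))
})

test_that("fragmentation bounds and the 100-nt floor hold", {
  cfg <- simulation_config(singleton_fraction = 1, seed = 8)
  tx <- setNames(vapply(1:30, function(i) rand_dna(1000), ""),
                 sprintf("t%02d", 1:30))
  fr <- fragment_transcripts(tx, cfg)
  expect_true(all(grepl("^singleton_", names(fr))))
  expect_true(all(nchar(fr) >= 400 & nchar(fr) <= 800))
  # sources >= 250 nt never yield fragments below 100 nt
  tx2 <- setNames(vapply(1:30, function(i) rand_dna(250), ""),
                  sprintf("s%02d", 1:30))
  fr2 <- fragment_transcripts(tx2, cfg)
  expect_true(all(nchar(fr2) >= 100))
  # fraction 0 leaves everything untouched
  cfg0 <- simulation_config(singleton_fraction = 0, seed = 8)
  expect_identical(fragment_transcripts(tx, cfg0)[seq_along(tx)], tx)
})

test_that("codon-pair simulation honours t = 0 and omega = 0", {
  cp0 <- simulate_codon_pair(100, omega = 0.4, t = 0, seed = 3)
  expect_identical(cp0$a, cp0$b)
  cp <- simulate_codon_pair(200, omega = 0, t = 0.4, seed = 5)
  aa <- function(s) {
    st <- seq(1, nchar(s), 3)
    unname(Biostrings::GENETIC_CODE[substring(s, st, st + 2)])
  }
  expect_identical(aa(cp$a), aa(cp$b))   # zero nonsynonymous differences
  expect_error(simulate_codon_pair(10, omega = -1, t = 0.1), "negative")
})
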