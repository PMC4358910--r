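# Isotig-to-model mapping, intron-retention calling, ORF finding, locus
# inference and isogroup size summaries.

test_that("a mature-mRNA isotig covers all exons and no introns", {
  m <- intron_model(6, seed = 23)
  a <- map_transcript_to_model(mature_mrna(m), m, isotig_id = "mat")
  ex <- grep("^exon", names(a$coverage))
  int <- grep("^intron", names(a$coverage))
  expect_true(all(a$coverage[ex] >= 0.99))
  expect_true(all(a$coverage[int] < 0.8))
  sc <- call_intron_retention(a, m)
  expect_identical(sc$retained_introns, integer(0))
  expect_true(sc$complete_orf)
})

test_that("a pre-mRNA isotig covers every feature and breaks the ORF", {
  m <- intron_model(6, seed = 23)
  a <- map_transcript_to_model(m$genomic_seq, m, isotig_id = "pre")
  expect_true(all(a$coverage >= 0.99))
  sc <- call_intron_retention(a, m)
  expect_identical(sc$retained_introns, seq_len(5L))
  expect_false(sc$complete_orf)
})

test_that("mapped blocks never overlap on the isotig and follow model order", {
  m <- intron_model(8, seed = 29)
  cfg <- simulation_config(retention_prob = 0.5, seed = 31)
  iso <- generate_splice_isoforms(m, cfg, n_isotigs = 10)
  feats <- c(paste0("exon", 1:8), paste0("intron", 1:7))
  for (id in names(iso$sequences)) {
    a <- map_transcript_to_model(iso$sequences[[id]], m, isotig_id = id)
    b <- a$blocks[a$blocks$kind != "unassigned", ]
    expect_true(all(diff(b$q_start) > 0))
    expect_true(all(b$q_start[-1] >= b$q_end[-nrow(b)]))
    # model order: genomic feature starts must increase along the isotig
    ft <- feature_table(m)
    expect_true(all(diff(ft$start[match(b$feature, ft$feature)]) > 0))
  }
})

test_that("retention calls recover the simulated truth and are monotone
           in the coverage threshold", {
  m <- intron_model(9, seed = 11)   # 8 introns
  cfg <- simulation_config(retention_prob = 0.5, seed = 37)
  iso <- generate_splice_isoforms(m, cfg, n_isotigs = 30)
  n_mismatch <- 0
  for (i in seq_len(nrow(iso$splice_truth))) {
    id <- iso$splice_truth$isotig_id[i]
    a <- map_transcript_to_model(iso$sequences[[id]], m, isotig_id = id)
    want <- as.integer(strsplit(iso$splice_truth$retained[i], ",")[[1]])
    got <- call_intron_retention(a, m)$retained_introns
    if (!identical(sort(got), sort(want))) n_mismatch <- n_mismatch + 1
    # monotonicity: a stricter threshold never adds introns
    strict <- call_intron_retention(a, m, min_coverage = 0.95)
    expect_true(all(strict$retained_introns %in% got))
  }
  expect_equal(n_mismatch, 0)
})

test_that("expected retained-intron count matches the binomial rate", {
  m <- intron_model(9, seed = 11)   # 8 introns
  cfg <- simulation_config(retention_prob = 0.4, seed = 41)
  iso <- generate_splice_isoforms(m, cfg, n_isotigs = 600)
  n_ret <- vapply(strsplit(iso$splice_truth$retained[-1], ","),
                  function(x) length(x[nzchar(x)]), 0L)
  p <- 0.4; I <- 8
  se <- sqrt(I * p * (1 - p) / length(n_ret))
  expect_lt(abs(mean(n_ret) - p * I), 3 * se)
})

test_that("find_longest_orf handles canonical and degenerate inputs", {
  orf <- find_longest_orf("ATGAAATAG")
  expect_identical(orf$interval, c(0L, 9L))
  expect_true(orf$complete)
  # no ATG: longest stop-free stretch, incomplete
  noatg <- "CCCCCCCCCCCCTAACCCCCC"
  orf2 <- find_longest_orf(noatg)
  expect_false(orf2$complete)
  expect_gt(orf2$length, 0)
  # reverse-strand ORF is found
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGAAAGGGTTTTAG")))
  orf3 <- find_longest_orf(rc)
  expect_true(orf3$complete)
  expect_identical(orf3$strand, "-")
  expect_identical(orf3$length, 15L)
})

test_that("embedded CDSs are recovered exactly from UTR context", {
  set.seed(43)
  cods <- setdiff(as.vector(outer(outer(c("A","C","G","T"),
                                        c("A","C","G","T"), paste0),
                                  c("A","C","G","T"), paste0)),
                  c("TAA", "TAG", "TGA"))
  n_exact <- 0
  for (rep in 1:100) {
    cfg <- simulation_config(n_genes = 1, exon_count_range = c(1, 1),
                             exon_len_range = c(400, 700), seed = rep)
    m <- generate_gene_models(cfg)[[1]]
    orf <- find_longest_orf(mature_mrna(m))
    if (orf$complete && identical(orf$interval, m$cds)) n_exact <- n_exact + 1
  }
  expect_equal(n_exact, 100)
})

test_that("a single-locus isogroup infers one locus and no chimeras", {
  m <- intron_model(9, seed = 11)
  cfg <- simulation_config(retention_prob = 0.5, seed = 47)
  iso <- generate_splice_isoforms(m, cfg, n_isotigs = 8)
  inf <- infer_locus_count(list(isogroup_id = m$gene_id,
                                isotigs = iso$sequences), m)
  expect_identical(inf$n_loci, 1L)
  expect_length(inf$chimeric_isotigs, 0)
  expect_true(all(inf$exon_variant_counts <= 1))
})

test_that("two diverged paralogs and cross-paralog chimeras are detected", {
  set.seed(53)
  m <- intron_model(7, seed = 59)
  cfg <- simulation_config(retention_prob = 0, seed = 61)
  mat1 <- mature_mrna(m)
  # paralog 2: 5% diverged copy of the locus
  mat2 <- mutate_dna(mat1, 0.05)
  # chimera: first half from paralog 1, second half from paralog 2
  half <- nchar(mat1) %/% 2
  chim <- paste0(substr(mat1, 1, half), substr(mat2, half + 1, nchar(mat2)))
  tigs <- c(p1a = mat1, p1b = mat1, p2a = mat2, p2b = mat2, chi = chim)
  inf <- infer_locus_count(list(isogroup_id = "two_loci", isotigs = tigs),
                           m)
  expect_identical(inf$n_loci, 2L)
  expect_true("chi" %in% inf$chimeric_isotigs)
  expect_false(any(c("p1a", "p1b") %in% inf$chimeric_isotigs))
  # invariance to isotig input order
  inf2 <- infer_locus_count(list(isogroup_id = "two_loci",
                                 isotigs = rev(tigs)), m)
  expect_identical(inf2$n_loci, 2L)
  expect_setequal(inf2$chimeric_isotigs, inf$chimeric_isotigs)
})

test_that("a single isotig gives one locus by construction", {
  m <- intron_model(5, seed = 67)
  inf <- infer_locus_count(list(isogroup_id = "solo",
                                isotigs = c(x = mature_mrna(m))), m)
  expect_identical(inf$n_loci, 1L)
})

test_that("isogroup size summary counts strict thresholds and the mean", {
  groups <- data.frame(
    isotig_id = sprintf("i%03d", 1:163),
    isogroup_id = rep(paste0("G", 1:4), c(5, 11, 46, 101)))
  s <- isogroup_size_summary(groups)
  expect_identical(unname(s$counts), c(3L, 2L, 1L))
  expect_equal(s$mean_isotigs, 163 / 4)
  s0 <- isogroup_size_summary(groups[0, ])
  expect_identical(unname(s0$counts), c(0L, 0L, 0L))
  expect_true(is.na(s0$mean_isotigs))
})

test_that("isotigs-per-isogroup allocation hits the configured mean", {
  sizes <- allocate_isogroup_sizes(40, 2.1, seed = 71)
  expect_true(all(sizes >= 1))
  groups <- data.frame(isotig_id = sprintf("i%03d", seq_len(sum(sizes))),
                       isogroup_id = rep(sprintf("g%02d", 1:40), sizes))
  s <- isogroup_size_summary(groups)
  expect_lt(abs(s$mean_isotigs - 2.1), 0.05)
  expect_identical(allocate_isogroup_sizes(40, 2.1, seed = 71), sizes)
})
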