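# Seed index, nucleotide and translated search, and the exact
# Smith-Waterman oracle (checked against an independent implementation).

test_that("seed index counts positions and skips N-containing words", {
  idx <- build_seed_index(c(s1 = "ACGTACGT"),
                          search_params(word_size = 4))
  hits <- do.call(rbind, lapply(c("ACGT", "CGTA", "GTAC", "TACG"),
                                function(k) seed_lookup(idx, k)))
  expect_identical(nrow(hits), 5L)   # length - k + 1 positions
  expect_identical(seed_lookup(idx, "ACGT")$pos, c(1L, 5L))
  idx2 <- build_seed_index(c(s1 = "ACGTNNNNACGT"),
                           search_params(word_size = 4))
  expect_identical(seed_lookup(idx2, "ACGT")$pos, c(1L, 9L))
  expect_identical(nrow(seed_lookup(idx2, "GTNN")), 0L)
  expect_error(build_seed_index(character(0)), "empty")
})

test_that("indexed k-mer lookup agrees with a brute-force scan", {
  set.seed(31)
  subs <- setNames(vapply(1:50, function(i) rand_dna(500), ""),
                   sprintf("s%03d", 1:50))
  idx <- build_seed_index(subs, search_params())
  for (probe in 1:25) {
    src <- sample(names(subs), 1)
    at <- sample(nchar(subs[[src]]) - 10, 1)
    kmer <- substr(subs[[src]], at, at + 10)
    got <- seed_lookup(idx, kmer)
    want <- do.call(rbind, lapply(names(subs), function(id) {
      m <- gregexpr(kmer, subs[[id]], fixed = TRUE)[[1]]
      if (m[1] == -1) return(NULL)
      # gregexpr misses overlapping occurrences; rescan positionally
      pos <- which(vapply(seq_len(nchar(subs[[id]]) - 10), function(p)
        substr(subs[[id]], p, p + 10) == kmer, TRUE))
      data.frame(subject_id = id, pos = pos)
    }))
    expect_identical(got[order(got$subject_id, got$pos), ],
                     want[order(want$subject_id, want$pos), ],
                     ignore_attr = TRUE)
  }
})

test_that("an identical query yields one full-length perfect HSP", {
  set.seed(7)
  subs <- setNames(vapply(1:5, function(i) rand_dna(300), ""),
                   paste0("s", 1:5))
  idx <- build_seed_index(subs, search_params())
  h <- search_nucleotide(c(q = subs[["s3"]]), idx)
  top <- h[1, ]
  expect_identical(top$subject_id, "s3")
  expect_identical(top$strand, "+")
  expect_equal(top$pident, 100)
  expect_identical(c(top$q_start, top$q_end), c(0L, 300L))
  expect_lt(top$evalue, 1e-10)
})

test_that("a reverse-complement query scores identically on the minus strand", {
  set.seed(8)
  subs <- setNames(vapply(1:5, function(i) rand_dna(300), ""),
                   paste0("s", 1:5))
  idx <- build_seed_index(subs, search_params())
  fwd <- search_nucleotide(c(q = subs[["s2"]]), idx)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(subs[["s2"]])))
  rev <- search_nucleotide(c(q = rc), idx)
  expect_identical(rev$strand[1], "-")
  expect_identical(rev$raw_score[1], fwd$raw_score[1])
  expect_identical(rev$subject_id[1], fwd$subject_id[1])
})

test_that("nucleotide search score is symmetric between directions", {
  set.seed(9)
  params <- search_params()
  for (rep in 1:5) {
    a <- rand_dna(300)
    b <- mutate_dna(a, 0.1)
    h_ab <- search_nucleotide(c(q = a),
                              build_seed_index(c(s = b), params), params)
    h_ba <- search_nucleotide(c(q = b),
                              build_seed_index(c(s = a), params), params)
    expect_identical(h_ab$raw_score[1], h_ba$raw_score[1])
  }
})

test_that("halving the database size halves the e-value at fixed score", {
  set.seed(10)
  subs <- setNames(vapply(1:4, function(i) rand_dna(400), ""),
                   paste0("s", 1:4))
  params <- search_params()
  q <- c(q = subs[["s1"]])
  h_full <- search_nucleotide(q, build_seed_index(subs, params), params)
  h_half <- search_nucleotide(q, build_seed_index(subs[1:2], params),
                              params)
  i <- which(h_full$subject_id == "s1")[1]
  j <- which(h_half$subject_id == "s1")[1]
  expect_identical(h_full$raw_score[i], h_half$raw_score[j])
  expect_equal(h_full$evalue[i] / h_half$evalue[j], 2)
})

test_that("the exact oracle matches an independent quadratic DP", {
  set.seed(11)
  params <- search_params()
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                  mismatch = -2)
  for (rep in 1:10) {
    a <- rand_dna(200)
    b <- if (rep <= 5) rand_dna(200) else mutate_dna(a, 0.2)
    r <- smith_waterman_oracle(a, b, params)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
    expect_equal(r$score, Biostrings::score(pa))
  }
  expect_equal(smith_waterman_oracle(strrep("A", 50), strrep("A", 50),
                                     params)$score, 50)
  expect_equal(smith_waterman_oracle("ACGT", "TTTT", params)$score, 1)
  expect_error(smith_waterman_oracle(strrep("A", 4000), strrep("A", 4000)),
               "size guard")
})

test_that("heuristic top hits reach at least 95% of the exact optimum", {
  set.seed(12)
  params <- search_params()
  for (rep in 1:20) {
    len <- sample(150:400, 1)
    a <- rand_dna(len)
    b <- mutate_dna(a, runif(1, 0, 0.15))
    idx <- build_seed_index(c(s = b), params)
    h <- search_nucleotide(c(q = a), idx, params)
    oracle <- smith_waterman_oracle(a, b, params)
    expect_gte(h$raw_score[1], 0.95 * oracle$score)
  }
})

test_that("translated search finds an exact protein in frame +1 and its
           reverse complement in a negative frame", {
  set.seed(13)
  cods <- setdiff(as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                        paste0), c("A","C","G","T"), paste0)),
                  c("TAA", "TAG", "TGA"))
  nt <- paste(sample(cods, 120, TRUE), collapse = "")
  st <- seq(1, nchar(nt), 3)
  prot <- paste(Biostrings::GENETIC_CODE[substring(nt, st, st + 2)],
                collapse = "")
  h <- search_translated("protein-query-vs-nt-db", c(p = prot),
                         c(n = nt))
  expect_identical(h$frame[1], 1L)
  expect_equal(h$pident[1], 100)
  expect_identical(c(h$q_start[1], h$q_end[1]), c(0L, 120L))
  expect_identical(c(h$s_start[1], h$s_end[1]), c(0L, 360L))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  h2 <- search_translated("protein-query-vs-nt-db", c(p = prot),
                          c(n = rc))
  expect_lt(h2$frame[1], 0L)
  expect_identical(h2$raw_score[1], h$raw_score[1])
})

test_that("translated best HSP tracks the exact protein-level optimum", {
  set.seed(14)
  params <- search_params()
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
           "S","T","W","Y","V")
  codon_of <- split(names(Biostrings::GENETIC_CODE),
                    unname(Biostrings::GENETIC_CODE))
  for (rep in 1:10) {
    prot <- paste(sample(aas, 150, TRUE), collapse = "")
    mut <- strsplit(prot, "")[[1]]
    hit <- which(runif(150) < 0.1)
    for (i in hit) mut[i] <- sample(setdiff(aas, mut[i]), 1)
    nt <- paste(vapply(mut, function(a) sample(codon_of[[a]], 1), ""),
                collapse = "")
    h <- search_translated("protein-query-vs-nt-db", c(p = prot),
                           c(n = nt), params)
    oracle <- smith_waterman_oracle(prot, paste(mut, collapse = ""),
                                    params, mode = "protein")
    expect_gte(h$raw_score[1], 0.95 * oracle$score)
  }
})

test_that("HSP TSV round-trips through the outfmt-6-style writer", {
  set.seed(15)
  subs <- setNames(vapply(1:3, function(i) rand_dna(250), ""),
                   paste0("s", 1:3))
  h <- search_nucleotide(setNames(subs, paste0("q", 1:3)),
                         build_seed_index(subs, search_params()))
  f <- tempfile(fileext = ".tsv")
  write_hsp_tsv(h, f)
  h2 <- read_hsp_tsv(f)
  expect_equal(as.data.frame(h), as.data.frame(h2), tolerance = 1e-12)
  unlink(f)
})
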