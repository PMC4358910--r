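# Reciprocal-best-hit pairing, the 1%-bin similarity histogram and the
# conserved-subset selection.

# minimal hand-built hit tables (already canonically sorted on build)
mk_hits <- function(df) {
  df$strand <- "+"
  df$q_start <- 0L; df$q_end <- 100L
  df$s_start <- 0L; df$s_end <- 100L
  df$raw_score <- df$bit_score
  df$evalue <- 1e-30 / df$bit_score
  df$n_identical <- round(df$pident)
  df$aln_len <- 100L
  df <- df[order(df$query_id, -df$bit_score, -df$aln_len, df$subject_id), ]
  class(df) <- c("hsp_table", "data.frame")
  df
}

test_that("an exact-copy species yields the identity map at similarity 100", {
  set.seed(16)
  a <- setNames(vapply(1:6, function(i) rand_dna(300), ""),
                paste0("g", 1:6))
  params <- search_params()
  h_ab <- search_nucleotide(a, build_seed_index(a, params), params)
  pairs <- reciprocal_best_hits(h_ab, h_ab)
  expect_identical(pairs$id_a, pairs$id_b)
  expect_identical(sort(pairs$id_a), sort(names(a)))
  expect_true(all(pairs$similarity == 100))
})

test_that("a non-mutual best hit produces no pair", {
  ab <- mk_hits(data.frame(query_id = "a1", subject_id = "b1",
                           bit_score = 100, pident = 95))
  ba <- mk_hits(data.frame(query_id = "b1",
                           subject_id = c("a2", "a1"),
                           bit_score = c(120, 100), pident = c(97, 95)))
  expect_identical(nrow(reciprocal_best_hits(ab, ba)), 0L)
  # and the mutual case does pair
  ba2 <- mk_hits(data.frame(query_id = "b1", subject_id = "a1",
                            bit_score = 100, pident = 95))
  expect_identical(nrow(reciprocal_best_hits(ab, ba2)), 1L)
})

test_that("hits referencing unknown ids raise an error", {
  ab <- mk_hits(data.frame(query_id = "a1", subject_id = "b1",
                           bit_score = 10, pident = 90))
  ba <- mk_hits(data.frame(query_id = "b1", subject_id = "a1",
                           bit_score = 10, pident = 90))
  expect_error(reciprocal_best_hits(ab, ba, known_a = "aX"), "unknown")
  expect_silent(reciprocal_best_hits(ab, ba, known_a = "a1",
                                     known_b = "b1"))
})

test_that("RBH output is symmetric and injective on the fixture", {
  fx <- rbh_fixture()
  pairs <- fx$pairs
  expect_false(anyDuplicated(pairs$id_a) > 0)
  expect_false(anyDuplicated(pairs$id_b) > 0)
  # transpose symmetry
  tp <- reciprocal_best_hits(fx$hits_ba, fx$hits_ab)
  expect_setequal(paste(pairs$id_a, pairs$id_b),
                  paste(tp$id_b, tp$id_a))
  # similarity equals the supporting HSP identity
  expect_equal(pairs$similarity,
               100 * pairs$hsp_n_identical / pairs$hsp_aln_len)
  # the two search directions agree on similarity within half a point
  ba_best <- fx$hits_ba[!duplicated(fx$hits_ba$query_id), ]
  back <- ba_best$pident[match(pairs$id_b, ba_best$query_id)]
  expect_lt(max(abs(pairs$similarity - back)), 0.5)
})

test_that("histogram bins, subtotals, median and sentinel behave as defined", {
  pairs <- data.frame(id_a = c("i1", "i2", "s1"),
                      id_b = paste0("b", 1:3),
                      similarity = c(87.2, 87.9, 91.0),
                      a_class = c("isotig", "isotig", "singleton"))
  h <- similarity_histogram(pairs)
  expect_identical(unname(h$counts[h$bin_lower == 87]), 2L)
  expect_identical(unname(h$counts[h$bin_lower == 91]), 1L)
  expect_equal(h$median, 87.9)
  expect_identical(sum(h$counts), 3L)
  expect_identical(colSums(h$by_class), as.numeric(h$counts),
                   ignore_attr = TRUE)
  # similarity 100 falls into the last bin
  h100 <- similarity_histogram(data.frame(id_a = "i", id_b = "b",
                                          similarity = 100,
                                          a_class = "isotig"))
  expect_identical(unname(h100$counts[h100$bin_lower == 99]), 1L)
  expect_equal(h100$median, 100)
  # empty sentinel
  h0 <- similarity_histogram(pairs[0, ])
  expect_identical(h0$n, 0L)
  expect_true(is.na(h0$median))
})

test_that("histogram counts always sum to the pair count on the fixture", {
  fx <- rbh_fixture()
  h <- similarity_histogram(fx$pairs)
  expect_identical(sum(h$counts), nrow(fx$pairs))
  expect_identical(colSums(h$by_class), as.numeric(h$counts),
                   ignore_attr = TRUE)
})

test_that("conserved selection is strict, class-filtered and monotone", {
  pairs <- data.frame(id_a = c("i1", "i2", "s1"),
                      id_b = paste0("b", 1:3),
                      similarity = c(93.0, 95.5, 99.0),
                      a_class = c("isotig", "isotig", "singleton"))
  sel <- select_conserved(pairs, threshold = 93)
  expect_identical(sel$id_a, "i2")        # 93.0 excluded, singleton dropped
  expect_identical(select_conserved(pairs, 0)$id_a, c("i1", "i2"))
  withsing <- select_conserved(pairs, 93, isotigs_only = FALSE)
  expect_setequal(withsing$id_a, c("i2", "s1"))
  # monotone in the threshold
  fx <- rbh_fixture()
  sizes <- vapply(c(80, 85, 90, 93, 96),
                  function(t) nrow(select_conserved(fx$pairs, t)), 0L)
  expect_true(all(diff(sizes) <= 0))
})
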