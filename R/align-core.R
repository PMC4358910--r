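# Alignment core: alphabets, scoring, Smith-Waterman wrappers and
# Karlin-Altschul statistics shared by the nucleotide and translated search.

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")
.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z",
                  "X", "*")
.AA_AMBIG_FROM <- 20L   # codes >= 20 (B, Z, X, *) never count as identical
.DNA_AMBIG_FROM <- 4L   # code 4 (N) never counts as identical

.encode_lookup <- function(alphabet) {
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt(paste(alphabet, collapse = ""))] <- seq_along(alphabet) - 1L
  lut[utf8ToInt(tolower(paste(alphabet, collapse = "")))] <-
    seq_along(alphabet) - 1L
  lut
}
.DNA_LUT <- .encode_lookup(.DNA_ALPHABET)
.AA_LUT <- .encode_lookup(.AA_ALPHABET)

encode_seq <- function(x, mode = c("nucleotide", "protein")) {
  mode <- match.arg(mode)
  lut <- if (mode == "nucleotide") .DNA_LUT else .AA_LUT
  codes <- lut[utf8ToInt(x)]
  if (anyNA(codes))
    stop("sequence contains characters outside the ", mode, " alphabet")
  codes
}

.dna_score_matrix <- function(match, mismatch) {
  m <- matrix(mismatch, 5L, 5L, dimnames = list(.DNA_ALPHABET, .DNA_ALPHABET))
  diag(m)[1:4] <- match
  m["N", "N"] <- mismatch  # N never rewarded
  m
}

.protein_score_matrix <- function(name = "BLOSUM62") {
  e <- new.env()
  data(list = name, package = "Biostrings", envir = e)
  full <- get(name, envir = e)
  full[.AA_ALPHABET, .AA_ALPHABET]
}

# Karlin-Altschul calibration constants, fixed per scoring scheme (ungapped
# published values for +1/-2 nucleotide scoring; standard gapped BLOSUM62
# values for protein mode). Only the e-value threshold behaviour matters
# downstream, so these are treated as calibration constants, not recomputed.
.ka_constants <- function(mode) {
  if (mode == "nucleotide") list(lambda = 1.28, K = 0.46)
  else list(lambda = 0.267, K = 0.041)
}

ka_evalue <- function(raw_score, m, n, mode = "nucleotide") {
  kc <- .ka_constants(mode)
  kc$K * as.numeric(m) * as.numeric(n) * exp(-kc$lambda * raw_score)
}

ka_bit_score <- function(raw_score, mode = "nucleotide") {
  kc <- .ka_constants(mode)
  (kc$lambda * raw_score - log(kc$K)) / log(2)
}

#' Search parameters for the seed-and-extend similarity search
#'
#' Container for the tunable parameters of [search_nucleotide()],
#' [search_translated()] and [smith_waterman_oracle()]. Defaults follow
#' common BLASTN conventions: word size 11 (nucleotide) or 3 (protein),
#' match/mismatch +1/-2, gap existence 5 and extension 2 per residue, and
#' an expectation-value cutoff of 1e-10.
#'
#' @param word_size Seed k-mer length; `NULL` selects 11 (nucleotide) or 3
#'   (protein) depending on the search mode.
#' @param match,mismatch Nucleotide match and mismatch scores.
#' @param gap_open,gap_extend Affine gap penalties (positive numbers); a gap
#'   of length L costs `gap_open + L * gap_extend`.
#' @param band Half-width padding (in diagonals) added around the seeded
#'   diagonal cluster during gapped extension; plays the role of an X-drop
#'   cutoff by bounding how far extensions may wander off-diagonal.
#' @param evalue_threshold Expectation-value cutoff; HSPs above it are
#'   discarded.
#' @param protein_matrix Name of the protein substitution matrix (a
#'   `Biostrings` data set; BLOSUM62 semantics).
#' @param neighbor_threshold Minimum BLOSUM score of a protein seed word
#'   against the query word for neighbourhood seeding.
#' @param ungapped_cutoff Minimum ungapped run score along the seeded
#'   diagonals before gapped extension is attempted; `NULL` (default)
#'   picks 30 (nucleotide) / 35 (protein), disabled for very short
#'   queries.
#' @return An object of class `search_params`.
#' @export
search_params <- function(word_size = NULL, match = 1, mismatch = -2,
                          gap_open = 5, gap_extend = 2, band = 32,
                          evalue_threshold = 1e-10,
                          protein_matrix = "BLOSUM62",
                          neighbor_threshold = 11,
                          ungapped_cutoff = NULL) {
  stopifnot(evalue_threshold > 0, gap_open >= 0, gap_extend >= 0, band >= 1)
  p <- list(word_size = word_size, match = match, mismatch = mismatch,
            gap_open = gap_open, gap_extend = gap_extend, band = band,
            evalue_threshold = evalue_threshold,
            protein_matrix = protein_matrix,
            neighbor_threshold = neighbor_threshold,
            ungapped_cutoff = ungapped_cutoff)
  class(p) <- "search_params"
  p
}

.word_size <- function(params, mode) {
  k <- params$word_size %||% if (mode == "nucleotide") 11L else 3L
  if (mode == "nucleotide" && k < 4L) stop("word_size must be >= 4 (nt)")
  if (mode == "protein" && k < 2L) stop("word_size must be >= 2 (protein)")
  as.integer(k)
}

.score_matrix <- function(params, mode) {
  if (mode == "nucleotide") .dna_score_matrix(params$match, params$mismatch)
  else .protein_score_matrix(params$protein_matrix)
}

.sw_core <- function(a, b, params, mode, dlo = NULL, dhi = NULL) {
  qa <- encode_seq(a, mode)
  sb <- encode_seq(b, mode)
  ambig <- if (mode == "nucleotide") .DNA_AMBIG_FROM else .AA_AMBIG_FROM
  if (is.null(dlo)) dlo <- -length(qa)
  if (is.null(dhi)) dhi <- length(sb)
  c_sw_align(qa, sb, .score_matrix(params, mode),
             params$gap_open, params$gap_extend,
             as.integer(dlo), as.integer(dhi), ambig)
}

#' Exact local alignment oracle
#'
#' Full (unbanded) affine-gap Smith-Waterman local alignment, used as the
#' exact reference against which the seed-and-extend heuristic is tested.
#'
#' @param a,b Sequences (single character strings).
#' @param params A [search_params()] object.
#' @param mode `"nucleotide"` or `"protein"`.
#' @param score_only Skip the traceback and return only the optimal score
#'   (faster; intervals and identity come back `NA`).
#' @return A list with `score`, 0-based half-open `q_interval` and
#'   `s_interval`, `n_identical`, `aln_len` and `pident`.
#' @export
smith_waterman_oracle <- function(a, b, params = search_params(),
                                  mode = c("nucleotide", "protein"),
                                  score_only = FALSE) {
  mode <- match.arg(mode)
  if (as.numeric(nchar(a)) * nchar(b) > 1e7)
    stop("sequence product exceeds the 1e7 oracle size guard")
  if (score_only) {
    sc <- c_sw_score(encode_seq(a, mode), encode_seq(b, mode),
                     .score_matrix(params, mode),
                     params$gap_open, params$gap_extend)
    return(list(score = sc, q_interval = c(NA_integer_, NA_integer_),
                s_interval = c(NA_integer_, NA_integer_),
                n_identical = NA_integer_, aln_len = NA_integer_,
                pident = NA_real_))
  }
  r <- .sw_core(a, b, params, mode)
  list(score = r$score,
       q_interval = c(r$q_begin, r$q_end),
       s_interval = c(r$s_begin, r$s_end),
       n_identical = r$n_identical, aln_len = r$aln_len,
       pident = if (r$aln_len > 0) 100 * r$n_identical / r$aln_len else NA_real_)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
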