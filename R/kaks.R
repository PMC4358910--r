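# Nei-Gojobori (1986) Ka/Ks on pairs of in-frame coding sequences.
# Synonymous/nonsynonymous site counts per codon (changes to stop codons
# count as nonsynonymous), pathway-averaged difference counts for codon
# pairs differing at 2-3 positions (pathways through stop codons excluded;
# codon pairs whose every pathway is blocked are excluded and counted),
# and Jukes-Cantor correction d = -(3/4) ln(1 - (4/3) p).

.codon_aa <- local({
  gc <- NULL
  function(codon) {
    if (is.null(gc)) gc <<- Biostrings::GENETIC_CODE
    unname(gc[codon])
  }
})

.ng86_cache <- new.env(parent = emptyenv())

.ng86_site_table <- function() {
  if (!is.null(.ng86_cache$sites)) return(.ng86_cache$sites)
  cods <- .NONSTOP_CODONS
  s <- vapply(cods, function(cod) {
    aa <- .codon_aa(cod)
    syn <- 0
    for (pos in 1:3) {
      base <- substr(cod, pos, pos)
      for (alt in setdiff(.BASES, base)) {
        nb <- cod
        substr(nb, pos, pos) <- alt
        if (!(nb %in% .STOPS) && .codon_aa(nb) == aa) syn <- syn + 1
      }
    }
    syn / 3
  }, numeric(1))
  .ng86_cache$sites <- cbind(s_sites = s, n_sites = 3 - s)
  rownames(.ng86_cache$sites) <- cods
  .ng86_cache$sites
}

# pathway-averaged (Sd, Nd) for one ordered codon pair; NA when every
# mutational pathway passes through a stop codon
.ng86_pair_counts <- function(c1, c2) {
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(diff_pos)
  if (nd == 0L) return(c(0, 0))
  perms <- switch(nd,
                  list(diff_pos),
                  list(diff_pos, rev(diff_pos)),
                  {
                    p <- diff_pos
                    list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
                         p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
                  })
  tot_s <- 0; tot_n <- 0; n_ok <- 0L
  for (ord in perms) {
    cur <- c1; s <- 0; n <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (nxt %in% .STOPS) { ok <- FALSE; break }
      if (.codon_aa(nxt) == .codon_aa(cur)) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n; n_ok <- n_ok + 1L }
  }
  if (n_ok == 0L) return(c(NA_real_, NA_real_))
  c(tot_s / n_ok, tot_n / n_ok)
}

.ng86_pair_tables <- function() {
  if (!is.null(.ng86_cache$Sd)) return(list(Sd = .ng86_cache$Sd,
                                            Nd = .ng86_cache$Nd))
  cods <- .NONSTOP_CODONS
  k <- length(cods)
  Sd <- matrix(NA_real_, k, k, dimnames = list(cods, cods))
  Nd <- Sd
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j < i) { Sd[i, j] <- Sd[j, i]; Nd[i, j] <- Nd[j, i]; next }
    v <- .ng86_pair_counts(cods[i], cods[j])
    Sd[i, j] <- v[1]; Nd[i, j] <- v[2]
  }
  .ng86_cache$Sd <- Sd; .ng86_cache$Nd <- Nd
  list(Sd = Sd, Nd = Nd)
}

#' NG86 synonymous/nonsynonymous site counts of codons
#'
#' For each position of a codon, the fraction of the three possible
#' single-nucleotide changes that are synonymous contributes 1/3 of a
#' synonymous site; changes to stop codons count as nonsynonymous.
#'
#' @param codons Character vector of non-stop codons over A/C/G/T.
#' @return Matrix with columns `s_sites` and `n_sites` (rows sum to 3).
#' @export
ng86_sites <- function(codons) {
  codons <- toupper(codons)
  if (any(codons %in% .STOPS)) stop("stop codon passed to ng86_sites")
  tab <- .ng86_site_table()
  bad <- !(codons %in% rownames(tab))
  if (any(bad)) stop("invalid codon: ", codons[bad][1])
  tab[codons, , drop = FALSE]
}

#' @rdname ng86_sites
#' @param codon A single codon.
#' @export
count_sites_ng86 <- function(codon) {
  v <- ng86_sites(codon)
  c(s_sites = unname(v[1, "s_sites"]), n_sites = unname(v[1, "n_sites"]))
}

#' Codon alignment of two in-frame coding sequences
#'
#' @param a,b Aligned DNA sequences of equal length divisible by 3; gap
#'   (`-`) or ambiguity in either sequence, or a stop codon in either,
#'   excludes the whole codon column.
#' @return A `codon_alignment` object.
#' @export
codon_alignment <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("aligned sequences must have equal length")
  if (nchar(a) %% 3 != 0) stop("alignment length must be divisible by 3")
  n <- nchar(a) %/% 3
  st <- seq(1L, by = 3L, length.out = n)
  ca <- substring(a, st, st + 2L)
  cb <- substring(b, st, st + 2L)
  clean <- function(x) grepl("^[ACGT]{3}$", x) & !(x %in% .STOPS)
  used <- clean(ca) & clean(cb)
  structure(list(codons_a = ca, codons_b = cb, used = used),
            class = "codon_alignment")
}

#' Nei-Gojobori (NG86) Ka/Ks with Jukes-Cantor correction
#'
#' Site counts S and N are averaged between the two sequences over the
#' usable codon columns; differences at codons differing at one position
#' are classified directly, at 2-3 positions by equal-weight averaging over
#' all stop-free mutational pathways (codon pairs with no stop-free
#' pathway are excluded and counted). Proportions ps = Sd/S and pn = Nd/N
#' are Jukes-Cantor corrected, d = -(3/4) ln(1 - (4/3) p); the ratio
#' dn/ds is `NA` when ds is zero or a correction is undefined (p >= 3/4).
#'
#' @param x A `codon_alignment`, or the first of two aligned sequences.
#' @param y Second sequence when `x` is a character sequence.
#' @return A `kaks_result` list: S, N, Sd, Nd, ps, pn, ds, dn, ratio,
#'   codons_used, codons_excluded (columns masked or pathway-blocked).
#' @export
kaks_ng86 <- function(x, y = NULL) {
  aln <- if (inherits(x, "codon_alignment")) x else codon_alignment(x, y)
  ca <- aln$codons_a[aln$used]
  cb <- aln$codons_b[aln$used]
  n_masked <- sum(!aln$used)
  if (length(ca) == 0L) stop("no usable codon columns")
  tabs <- .ng86_pair_tables()
  sd_v <- tabs$Sd[cbind(ca, cb)]
  nd_v <- tabs$Nd[cbind(ca, cb)]
  blocked <- is.na(sd_v)
  ca <- ca[!blocked]; cb <- cb[!blocked]
  sd_v <- sd_v[!blocked]; nd_v <- nd_v[!blocked]
  if (length(ca) == 0L) stop("no usable codon columns after pathway exclusion")
  st <- .ng86_site_table()
  S <- (sum(st[ca, "s_sites"]) + sum(st[cb, "s_sites"])) / 2
  N <- (sum(st[ca, "n_sites"]) + sum(st[cb, "n_sites"])) / 2
  Sd <- sum(sd_v); Nd <- sum(nd_v)
  ps <- Sd / S; pn <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ds <- jc(ps); dn <- jc(pn)
  ratio <- if (is.na(ds) || is.na(dn) || ds == 0) NA_real_ else dn / ds
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 ds = ds, dn = dn, ratio = ratio,
                 codons_used = length(ca),
                 codons_excluded = n_masked + sum(blocked)),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, digits = 4, ...) {
  cat("NG86 Ka/Ks over", x$codons_used, "codons (",
      x$codons_excluded, "excluded )\n")
  cat(sprintf("  S = %.2f  N = %.2f  Sd = %.2f  Nd = %.2f\n",
              x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  ds = %s  dn = %s  dn/ds = %s\n",
              format(x$ds, digits = digits),
              format(x$dn, digits = digits),
              format(x$ratio, digits = digits)))
  invisible(x)
}

#' Ka/Ks from a two-sequence aligned FASTA
#'
#' @param path FASTA with exactly two aligned, in-frame records.
#' @param tsv_path Optional path; when given, a one-line TSV of the result
#'   fields is written there.
#' @return A `kaks_result`.
#' @export
kaks_from_fasta <- function(path, tsv_path = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) != 2) stop("expected exactly two aligned sequences")
  res <- kaks_ng86(as.character(seqs[[1]]), as.character(seqs[[2]]))
  if (!is.null(tsv_path)) {
    write.table(as.data.frame(unclass(res)), tsv_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  res
}
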