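---
title: "orthosplice: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orthosplice: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it implements:
the models and their assumptions, the tunable parameters with their
defaults and units, what the synthetic data generator does and does not
emulate, the numerical choices, and the limitations we know about. It
states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The analysis the package supports

Two closely related species each have a transcript set: one assembled de
novo (isotigs grouped into isogroups, plus short singleton reads), one
possibly derived in silico from a genome annotation. Without a reference
genome for either species, the questions that can still be answered are
comparative: which transcripts are putative orthologs, how diverged are
they, which functional categories resist divergence, what hides inside
isogroups with extreme transcript counts (alternative splicing by intron
retention, or several confounded loci), what selective pressure acts on
recent paralog pairs, and whether a panel of reference genes is
concordantly present or absent in both species. Each stage is a module
with a plain function interface; `run_pipeline()` chains them over a
seeded simulation with TSV outputs and JSON provenance.

## Pairwise search

The search is a classic seed-and-extend heuristic with an exact oracle
beside it.

**Seeding.** Nucleotide mode indexes exact k-mers (`word_size`, default
11 nt; k-mers containing N are skipped) of the subject set and looks up
both the query and its reverse complement. Protein mode (used by the
six-frame translated searches) indexes exact 3-mers of the stop-free
translation segments and expands each query 3-mer to its BLOSUM62
neighbourhood (words scoring at least `neighbor_threshold = 11` against
it), the standard BLASTP configuration.

**Extension.** Seed hits for one (query, subject) pair are grouped by
alignment diagonal. A diagonal carrying at least two seeds (one for
queries too short to have two words) becomes a candidate; nearby
candidate diagonals are merged, and the candidate band, padded by
`band = 32` diagonals on each side, is handed to a banded affine-gap
Smith-Waterman (Rcpp) that returns the optimal local alignment within
the band with a full traceback. This "banded optimal extension" plays
the role that an X-drop cutoff plays in BLAST: it bounds how far the
extension may wander off the seeded diagonal, while being exact within
that corridor. It also makes HSP merging trivial — per (query, subject,
strand) only the best-scoring extension is reported, so overlapping HSPs
cannot occur. At most four candidate bands per pair are extended
(ranked by seed support); colinear homology concentrates its seeds on
one diagonal, so this cap only sheds noise.

**Scoring and statistics.** Defaults are match +1 / mismatch −2, gap
existence 5 and extension 2 per residue, BLOSUM62 for proteins. Percent
identity uses alignment columns (including gap columns) as the
denominator, the BLAST HSP convention; N and X positions never count as
identical. Expectation values use E = K·m·n·e^(−λS) with fixed
calibration constants (λ = 1.28, K = 0.46 for the +1/−2 nucleotide
scheme; λ = 0.267, K = 0.041 for gapped BLOSUM62). These are treated as
calibration constants, not re-derived: downstream analyses only depend
on the `evalue_threshold = 1e-10` cutoff behaving like the conventional
one, and the tests verify the exact property that halving the database
size halves E at fixed score. Ties among equal-score hits break by
longer alignment, then lexicographic subject id, which makes best-hit
selection — and therefore RBH output — fully deterministic.

**Oracle.** `smith_waterman_oracle()` is the same kernel with the band
opened to the full matrix (guarded at 10^7 cells), cross-checked in the
tests against `Biostrings::pairwiseAlignment()` as an independent
implementation. The acceptance suite measures heuristic-vs-oracle
top-hit agreement on simulated pairs up to 400 nt and 15% divergence.

## Reciprocal-best-hit orthology

A pair (a, b) is an ortholog call iff b is a's unique best hit A→B and a
is b's unique best hit B→A. Uniqueness is guaranteed by the search
tie-breaking. The similarity attached to a pair is the percent identity
of the supporting A→B HSP; the B→A value differs only by alignment
asymmetries and the tests assert the two directions agree within half a
percentage point. Histograms use 1%-wide bins [x, x+1) with 100 falling
in [99, 100]; the median is reported over all pairs (isotigs and
singletons together), with class subtotals kept per bin, because short
singleton fragments measure only local similarity and analyses of the
conserved subset therefore drop them first (`isotigs_only = TRUE` in
`select_conserved()`, strict `>` on the threshold, default 93%).

## GO enrichment

One-sided hypergeometric enrichment of a query id set against an
annotated reference: for a term with K carriers among N annotated
reference ids and k carriers among n annotated query ids, p is the
upper tail P(X ≥ k) (computed with `stats::phyper`). Only terms with at
least `min_mapping = 4` query carriers are tested; whether the minimum
applies to the query or the reference side is genuinely ambiguous in
common web tools, so it is configurable (`min_mapping_side`), with
"query" the default because it is the stricter reading for small query
sets. The tested family is adjusted with Benjamini-Yekutieli
(`stats::p.adjust(method = "BY")`), chosen over Benjamini-Hochberg
because GO terms are strongly dependent and BY controls FDR under
arbitrary dependence; significance is `p_adj <= 0.05`. Annotation maps
are flat id→term lists; ancestor propagation over an ontology DAG is
not implemented — inputs are expected to be already-propagated exports,
the common situation for the flat annotation files this workflow
consumes.

## Isogroup splicing analysis

`map_transcript_to_model()` aligns every model feature (exon or intron)
against the isotig with the exact local aligner, keeps features whose
best alignment scores at least `max(20, 0.35·feature_length)` with at
least 60% identity, and selects the highest-scoring colinear chain:
feature order must be preserved and isotig intervals must increase
(blocks may abut; residual overlaps up to 8 nt, which arise from
repeated boundary nucleotides, are trimmed). Isotig spans of 10+ nt
outside all chained blocks are labelled `unassigned`; model-order
inversions can never appear in a chain, so trans-rearranged isotigs
degrade to unassigned rather than producing misleading labels.

Retention: intron j is called retained iff its aligned coverage is at
least `min_coverage = 0.8`. The threshold is a package choice — a
positional criterion ("a block sitting between two exon blocks") needs
some cutoff to separate genuine retention from spurious short matches,
and 0.8 leaves room for ragged alignment ends while rejecting partial
hits; it is configurable and recorded in provenance.

ORF completeness: `find_longest_orf()` scans both strands, three frames
each, for the longest ATG-to-stop ORF (falling back to the longest
stop-free stretch, flagged incomplete, when no complete ORF exists). An
isotig is called ORF-complete when its longest ORF is complete, spans
at least 90% of the reference mature-mRNA coding length, *and* its
translation ends in the reference C-terminus (last 10 residues). The
third condition matters: an isotig retaining only a 3'-proximal intron
still contains a long ATG-to-stop ORF — truncated at a stop codon
inside the intron — and a pure length criterion would accept it. Ending
in intron-derived residues rather than the reference tail is what makes
such an ORF incorrect, so that is what is tested.

Locus inference: for each exon, the exon-overlapping block sequences of
all isotigs are collected, deduplicated, and single-linkage clustered
at `cluster_identity = 98` percent (identity computed over the shorter
sequence so full-length variants cluster despite trimmed ends). The 98%
default is chosen to lump alleles and residual sequencing noise while
splitting paralogs at a few percent divergence; it is configurable. The
locus-count estimate is the maximum per-exon cluster count. To compare
cluster labels across exons, clusters are ranked by their best identity
to the model's own exon sequence (label 1 = closest to the reference);
an isotig is chimeric iff, over exons with two or more clusters, it
draws blocks from two or more labels. This ranking is a heuristic: it
is stable when one locus is systematically closer to the reference
model than the other (the situation the generator creates and the
typical situation when the model comes from the better-conserved
paralog), but paralogs equidistant from the model could swap labels
between exons. Near-identical paralogs are a second caveat: below the
clustering threshold they collapse into one cluster and the locus count
undercounts — transcript evidence alone cannot resolve them, which is
why the output is an estimate with the per-exon counts attached.

## NG86 Ka/Ks

The estimator is Nei-Gojobori (1986) with Jukes-Cantor correction,
chosen as the transparent, assumption-light pairwise method appropriate
when the provenance of a published ratio is unknown: it makes the
counting explicit and its biases are well understood. Site counts are
fractional (per codon position, the fraction of the three possible
changes that are synonymous; mutations to stop codons count as
nonsynonymous), averaged between the two sequences. Codon pairs
differing at one position are classified directly; at 2–3 positions,
counts are averaged with equal weights over all orderings of the
changes whose intermediates avoid stop codons; a pair whose every
pathway passes through a stop is excluded and counted. Columns with a
gap, an ambiguity, or a stop in either sequence are excluded. The
correction d = −(3/4)·ln(1 − (4/3)·p) is undefined at p ≥ 3/4 and the
ratio dn/ds is undefined at ds = 0; both come back as `NA` sentinels
with the raw proportions still reported. The whole 61×61
pathway-averaged difference table is verified in the tests against an
independent recursive enumerator, and ω recovery is checked on
simulated codon pairs (500 codons, ω = 0.4, synonymous branch length
t = 0.3, 100 replicates — sized so the Monte-Carlo error of the mean is
well below the 0.08 tolerance while the suite stays fast).

## Presence/absence and concordance

A reference protein is called present in a transcriptome iff its best
forward hit (protein vs six-frame-translated transcripts) passes the
e-value threshold *and* the best reverse hit of that transcript
(translated transcript vs protein panel) returns the same protein.
Requiring reciprocity, not merely a forward hit, is the deliberate
default — it is the ortholog-grade criterion — and can be relaxed
(`require_reciprocal = FALSE`) for sensitivity analysis. The number of
transcripts passing both tests is retained (`n_supporting`) so
duplicated genes are visible as multi-transcript support. Every call
carries a `transcript_evidence_only` column: absence from a
transcriptome is evidence about expression capture, not proof of
genomic absence, and the schema says so explicitly. Two-species call
sets over the same panel reduce to a 2×2 concordance table.

## Read filter and reporting

`filter_reads()` implements the four-rule quality filter: phred ≥ 25,
length ≥ 100 nt, zero non-ACGT bases, longest homopolymer ≤ 8 nt,
applied in that order with the first failing rule logged per read.
Whether "phred ≥ 25" means the mean or the minimum per-read quality is
ambiguous in common tool descriptions; the package defaults to the mean
(`phred_mode = "mean"`), the usual reading for 454-era filters, and
exposes the minimum as an option. N50 uses the ≥-half-total convention
with ties resolved toward the smaller length, matching assembler
reports. `write_report()` only restates stage TSVs; it computes nothing
new.

## The synthetic generator: what it emulates, and what not

The generator's defaults are the study conditions the package is
designed around: 13% per-site divergence between the species (which
makes ~87% the expected ortholog identity and centres the histogram in
the 85–90% bins), a conserved subset of 20% of genes evolving at one
third of that rate (so that selection at >93% identity is enriched for
them), 10% of genes lost and 5% duplicated in species B (duplicates
diverge at twice the base rate after copying, so they remain separable
from orthologs in RBH), per-intron retention probability 0.5 for
splice-variant isogroups, a target mean of 2.1 isotigs per isogroup,
and 15% of transcripts emitted as singleton fragments — a value chosen
once as a realistic fragment load for a normalized 454 library.
Fragments are one uniform-random contiguous substring of 40–80% of the
source (a free choice; real singleton length distributions are not well
characterized beyond a lower cutoff) and never fall below 100 nt when
the source allows.

Gene models have 3–9 exons of 60–240 nt and introns of 50–200 nt by
default. Each mature mRNA carries a complete ORF constructed to be its
unique longest ORF (verified by rejection sampling at generation time),
with short ATG-free UTRs; each intron embeds stop codons in all three
reading frames, so intron retention always interrupts the frame — the
deliberate worst case for ORF-based detection of mis-spliced
transcripts. The mutation model is per-site uniform substitution to one
of the three alternatives with no back-mutation within a pass and no
indels (indels enter only via fragmentation); this keeps the
identity-divergence relationship analytically checkable (expected
pairwise difference equals the configured rate). Codon pairs for ω
recovery draw Poisson numbers of synonymous (t·S) and nonsynonymous
(ω·t·N) events placed uniformly over eligible single-nucleotide
changes, rejecting stops.

One config seed determines every output byte: each operation draws from
its own RNG stream derived by hashing the operation name into the seed,
so adding or reordering calls does not silently shift downstream
streams.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: 454 homopolymer sequencing
errors and quality profiles (reads are synthesized clean; the FASTQ
path exists only to exercise the filter), assembly artifacts such as
collapsed paralogs or chimeric misjoins beyond the explicit chimera
scenarios, insertions/deletions between orthologs, rate heterogeneity
along genes, codon usage bias, strand mixtures (generation is
plus-strand; strand handling is exercised in the search), and any
real GO structure (annotations in the pipeline are synthetic labels).
Results on real transcriptomes will additionally be limited by
assembly quality in ways these tests cannot measure.

## Problem sizes and determinism

The test and acceptance problem sizes are package choices balancing
statistical resolution against a comfortable laptop run: 200 simulated
pairs for heuristic-vs-oracle agreement, a 100-gene two-species fixture
for RBH/histogram/conserved-subset checks, 1000 replicates for the
enrichment null calibration, 200 isotigs on an 8-intron gene for the
splicing scenario, 100 replicates of 500 codons for ω recovery, and a
59-gene presence panel with 11 genes retained in both species. All are
driven by explicit seeds; `scripts/acceptance.R` derives every stream
from its single `--seed` argument.

## Known limitations

* The locus-count estimate undercounts paralogs more similar than the
  clustering threshold and relies on a reference-similarity ranking to
  align variant labels across exons (above).
* Karlin-Altschul constants are fixed per scoring scheme, not derived
  per database; e-values are calibrated for thresholding, not for
  cross-scheme comparison.
* The enrichment module does not propagate annotations over an
  ontology DAG; supply propagated annotations if ancestor counting is
  wanted.
* NG86 is a pairwise counting estimator: it saturates at high
  divergence (correction undefined at p ≥ 3/4) and ignores
  transition/transversion and codon-frequency effects by design.
* Ortholog simulation has no indels, so the search's gap handling is
  exercised by construction (fragment boundaries, translated frames)
  rather than by internal indels.
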