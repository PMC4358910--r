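Package: orthosplice
Title: Comparative Transcriptomics of Congeneric Species: Orthology,
    Intron Retention and Ka/Ks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing de novo transcriptomes of closely related
    species without a reference genome. Implements a self-contained
    seed-and-extend local similarity search (nucleotide and six-frame
    translated modes) with BLAST-like high-scoring segment pairs and
    Karlin-Altschul expectation values; reciprocal-best-hit ortholog
    identification with percent-identity distribution and conserved-subset
    analysis; hypergeometric GO-term enrichment with Benjamini-Yekutieli
    adjustment; isogroup-level alternative-splicing analysis (mapping
    assembled isotigs onto gene models, intron-retention calling, locus-count
    and chimera inference); Nei-Gojobori (NG86) Ka/Ks estimation with
    Jukes-Cantor correction; translated reciprocal presence/absence calling
    of reference gene panels; a read-quality filter; and a seeded synthetic
    dual-species transcriptome generator with machine-readable truth tables
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
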