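Package: evimotif
Title: Evidence-Ranked Discovery of Degenerate Sequence Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: De novo discovery of degenerate IUPAC consensus motifs from a
    genome-wide set of putative regulatory regions paired with quantitative
    per-region evidence of regulation (ChIP-chip P-values, ChIP-seq peak
    densities, or expression fold-changes).  Every non-degenerate 5-mer seeds
    an independent greedy search that varies motif length and degeneracy to
    maximise a gene-set-enrichment-style objective: the centred and scaled
    average evidence of the regions containing the motif.  Occurrence queries
    are answered by a suffix-array index with branching descent over
    degenerate symbols.  Includes PSSM construction from motif occurrences,
    similarity-and-co-occurrence clustering of redundant predictions,
    permutation significance with a Gamma tail approximation, ortholog-based
    conservation filtering, ChIP-seq peak preprocessing, a planted-motif
    data synthesiser, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Matrix,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
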