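Package: ssnsubfam
Title: Sequence Similarity Network Subfamily Delineation for Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates subfamilies within large protein families (modelled on
    CAZy glycoside hydrolase family 2) from all-vs-all pairwise similarity.
    Provides coverage filtering and greedy redundancy clustering of domain
    sequences, an internal Smith-Waterman aligner with Karlin-Altschul
    E-value statistics plus a reader for BLAST/DIAMOND tabular hits, a
    sequence-similarity-network threshold sweep scored by the weighted
    average closeness centrality of connected components, peak detection and
    threshold selection, rule-based subfamily release (30 representatives or
    one characterized member), split-tree tracking of component emergence,
    secretion-signal and functional-homogeneity summaries, a synthetic
    family generator with planted hierarchical subfamily structure, and a
    Michaelis-Menten kinetics module (nonlinear fit and linear-regression
    kcat/KM for non-saturating enzymes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
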