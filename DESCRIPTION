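Package: pattree
Title: Alignment-Free Phylogenies from Closed Sequential Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs phylogenetic trees from unaligned protein or
    nucleotide sequences without a multiple sequence alignment. Closed
    frequent sequential patterns with single-residue wildcards are mined
    from the sequence set by depth-first growth over projected databases,
    weighted by an inverse-document-frequency style score, and used as a
    feature space in which every sequence becomes a pattern vector.
    Pairwise Jensen-Shannon divergences between normalized vectors feed a
    Neighbor-Joining tree. Includes Robinson-Foulds tree comparison, a
    brute-force pattern enumerator used as a test oracle, and a
    tree-guided sequence-evolution simulator (substitutions plus indels)
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
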