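Package: otuclust
Title: Greedy Radius-Bounded Clustering of Highly Similar DNA Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Greedy incremental clustering of highly similar DNA sequences
    (e.g. 16S rRNA amplicon reads) under a guaranteed bound on the cluster
    radius, measured as unit-cost (semi-)global edit distance. The search for
    all unclustered sequences within a radius of a cluster representative is a
    depth-first traversal of the implicit trie over the lexicographically
    sorted sequence list, sharing threshold-banded dynamic-programming rows
    across common prefixes, and is screened by a completely sensitive k-mer
    spectrum filter organised as a binary tree over the sorted list. Per
    cluster, a star multiple sequence alignment is reconciled from the
    member-versus-representative pairwise alignments. Includes a seeded
    synthetic read-cloud generator with ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
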