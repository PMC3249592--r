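Package: polysup
Title: Polynomial Rooted Supertree Construction and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs rooted supertrees from collections of rooted
    phylogenetic trees with overlapping leaf sets using the polynomial
    graph-based methods Build, MinCut (MC), Modified MinCut (MMC), and
    Build-with-Distances (BWD) with the SAC and SACmax support functions.
    Includes branch-length reconciliation across input trees (alpha-trimmed
    mean, least squares, and minimax multiplicative constants),
    tree-comparison metrics (normalized Robinson-Foulds distance, rooted
    triplet distance, maximum agreement subtree score, resolution), and a
    self-contained simulation benchmark (Yule model trees with deviated
    branch rates and an outgroup, GTR+Gamma+I sequence evolution, random
    taxon deletion, neighbor-joining reconstruction of input trees).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    phangorn,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
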