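Package: ppibridge
Title: Network-Based Inference of Bridge Genes Between Seed Gene Sets on a
    Protein-Protein Interaction Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes genes that functionally link two seed gene sets
    (for example, the regeneration genes of two tissues) on a confidence-
    weighted protein-protein interaction network. Edges carry STRING-style
    combined scores that are transformed to weights so that Dijkstra
    shortest paths follow high-confidence interactions; inner nodes of the
    cross-set shortest paths are scored by a path-count betweenness,
    filtered by a degree-preserving permutation false discovery rate, and
    screened by a betweenness-ratio rule and a minimum-of-maxima direct
    interaction-score rule. Includes reproducible synthetic network
    fixtures with planted bridge nodes, per-pair and cross-pair reports,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
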