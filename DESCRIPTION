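Package: edgeodds
Title: Orientation Odds, Coherence and Dutch Books for Undirected Edges in Essential Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Makes undirected edges in essential graphs (CPDAGs summarising
    Markov equivalence classes of causal DAGs) quantitatively interpretable.
    Enumerates the DAG members of an equivalence class, computes edge
    orientation probabilities induced by a distribution over members, tests
    arbitrary per-edge orientation beliefs for coherence by linear
    programming, constructs Dutch-book bet packages against incoherent
    beliefs, and runs an exhaustive census of orientation-imbalanced
    undirected edges over all small DAGs (e.g. 4 nodes, 3 edges). Includes
    plain-text graph and CSV belief/bet readers and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    boot,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
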