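Package: csnet
Title: Condition Steiner Networks: Exact and Approximate Subnetwork Inference
    Across Biological Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the Condition Steiner Network problem family: finding
    minimum-weight subgraphs of a reference interaction network (for example a
    protein-protein interaction network) that satisfy condition-indexed
    connectivity demands, where each condition (time point, treatment, cell
    state) selects its own subset of active edges. Provides a flow-based
    integer linear programming solver for exact optima, a recursive-greedy
    approximation for monotonic single-source instances, the trivial
    union-of-shortest-paths heuristic, exact brute-force oracles for small
    instances, strict problem reductions between the shortest-path,
    Steiner-tree, prize-collecting and priority-Steiner formulations, and
    generators for hardness gadgets and synthetic PPI-like instances.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
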