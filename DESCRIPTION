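Package: qanalysis
Title: Q-Analysis of Simplicial Complexes for Higher-Order Network Structure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for Q-analysis of simplicial complexes, a framework for
    quantifying higher-order (multi-node) interactions in complex networks.
    Builds complexes from simplex lists or from graphs via maximal cliques,
    computes q-connectivity structure (first, second and third structure
    vectors), topological entropy, per-vertex topological dimensionality and
    simplex eccentricities, projects complexes back to graphs, and compares
    groups of networks with a consensus-network permutation test. Includes
    seeded generators for scale-free (preferential attachment) and
    configurational (Havel-Hakimi) network ensembles and a command-line
    interface over the toolkit.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
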