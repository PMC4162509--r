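Package: leaforder
Title: Modular Leaf Ordering and Evaluation for Dendrograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Choosing among the 2^(n-1) admissible leaf orders of an
    agglomerative clustering dendrogram. Implements modular leaf-ordering
    heuristics that re-orient every merge by the smallest or average
    preceding merge distance, alongside the default dendrogram orientation
    rules, a Gruvaeus-Wainer-style endpoint-greedy baseline and exact
    optimal leaf ordering by dynamic programming. Orderings are compared
    with drawn-line-length and data-ink-ratio metrics, Hamiltonian path
    length and anti-Robinson event counts; dendrograms and cluster heat
    maps are rendered as deterministic SVG. Includes seeded synthetic
    fixtures, the Fisher iris table, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
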