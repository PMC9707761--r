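Package: ehgm
Title: Exact Hypergraph Matching for Point-Set Correspondence and C.
    elegans Posture Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Globally optimal point-set correspondence under
    hypergraphical models of arbitrary degree, via an exact
    branch-and-bound search over injective assignments.  Includes
    geometric posture models (Sides, Pairs, Posture) for identifying
    seam-cell nuclei in coiled C. elegans embryos, time-dependent
    posture-template fitting from labeled corpora, a synthetic
    coiled-embryo generator for fully reproducible evaluation, and the
    top-x accuracy and cost-ratio evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
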