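Package: tdbnet
Title: Time-Delay Boolean Network Inference from Binary Expression Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and reconstruction of time-delay Boolean networks,
    a non-deterministic Boolean network model in which a regulator function
    can be a prerequisite for (rather than a determinant of) its target
    gene, so delayed activation shows up as free output bits in state
    transitions. Provides truth-table algebra for small Boolean functions,
    transition simulation with misclassification noise, exact
    identification from noise-free samples by count-table pattern matching,
    EM estimation of the misclassification probability under zero-cell
    hypotheses (p-scores), maximum-compatibility threshold selection, and
    binarization utilities for expression time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
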