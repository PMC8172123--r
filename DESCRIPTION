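Package: mrmcal
Title: Rule-Matrix Immune Simulation with Genetic-Algorithm Range Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reduced stochastic agent-based model of the endothelial-blood
    interface after injury whose cytokine interaction rules are encoded in a
    Model Rule Matrix, together with a real-valued genetic algorithm that
    calibrates the matrix to the range envelope of heterogeneous clinical
    cytokine time series.  Candidate parameterizations are scored by a
    range-difference fitness with a mortality term, non-viable candidates
    (death before the first clinical sampling time) are rejected, and every
    candidate whose replicate envelope lies inside the clinical ranges is
    retained as a member of a bioplausible ensemble.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
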