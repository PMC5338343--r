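Package: kinfp
Title: Single-Molecule Kinetic Fingerprinting for Point-Mutation Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule transient DNA-binding
    (kinetic fingerprinting) experiments for digital counting of point
    mutations. Generates ground-truth-labeled two-state binding trajectories
    and synthetic TIRF image stacks, extracts per-molecule intensity traces,
    idealizes them with a two-state Gaussian hidden Markov model, filters
    non-specific background molecules, classifies molecules as mutant or wild
    type from bound-state dwell statistics, models discrimination capability
    with a gamma dwell-time model and a Poisson event-count baseline, and
    quantifies mutant allele fractions from positive molecule counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
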