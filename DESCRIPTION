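Package: clampkit
Title: Patch-Clamp Phenotyping of Simulated and Recorded Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for whole-cell patch-clamp phenotyping of developing
    neurons, built around a conductance-based synthetic recording
    generator. Simulates current-clamp step families, voltage-clamp
    current families, and spontaneous excitatory postsynaptic current
    (EPSC) traffic for parameterized cells and labelled cohorts; extracts
    intrinsic excitability and spike-shape features (threshold, amplitude,
    full width at half maximum, fast afterhyperpolarization), capacitance
    and leak-subtracted sodium/potassium current-voltage curves, and
    synaptic event and network-burst statistics; and compares genotype
    cohorts across maturation time points with summary-statistic t-tests,
    empirical distribution comparisons, and trajectory grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
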