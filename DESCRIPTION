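Package: persistkit
Title: Quantifying Antibiotic Tolerance and Persistence from Kill Curves,
    Single-Cell Tracks and Cytometry, with an Alarmone-GTP Switch Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates antibiotic tolerance from persistence by decomposing
    biphasic kill curves into a two-subpopulation exponential death model and
    computing the persister-subtracted MDK99; detects switch-like entry into
    dormancy from single-cell length and reporter-fluorescence tracks; gates
    rare low-GTP (bright-reporter) subpopulations in flow-cytometry event
    tables; and generates all three kinds of input synthetically from a
    per-cell stochastic model of cooperative (p)ppGpp-GTP antagonism with
    genotype and treatment presets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    withr,
    deSolve,
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
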