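Package: cytosweep
Title: Deterministic Dynamics of Maternally Co-Inherited Symbionts and
    Mitochondria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-generation mean-field models of the joint dynamics of a
    facultative maternally inherited symbiont and the mitochondria it is
    co-transmitted with. Implements three host-symbiont interaction classes
    (fixed drive balanced by segregational loss, negatively
    frequency-dependent benefit with a fixed carriage cost, and cytoplasmic
    incompatibility with its bistable equilibria), closed-form resident
    equilibria and persistence criteria, linearized invasion analysis of a
    positively selected novel mitotype arising in infected or uninfected
    hosts, outcome classification by full-recursion simulation, trajectory
    and two-dimensional parameter-sweep experiments with tidy CSV output,
    ggplot2 figures, and a YAML-configured command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
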