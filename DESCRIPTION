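Package: vectoropt
Title: Temperature-Responsive Mosquito Population Dynamics and Genetic
    Biocontrol Release Scheduling
Version: 0.1.0
Authors@R:
    person("Joan", "Mercader", email = "jmercader@example.org",
           role = c("aut", "cre"))
Description: Simulates stage- and genotype-structured mosquito population
    dynamics driven by daily temperature series, with genetic biocontrol
    (RIDL-style dominant-lethal) male releases, and optimizes release
    schedules as deterministic or scenario-weighted stochastic nonlinear
    programs. The discrete dynamics used inside the optimizer are the same
    code that re-simulates a returned schedule, so optimized policies can be
    re-evaluated under alternative climate scenarios within one framework.
    Includes a synthetic daily-temperature scenario generator (annual
    sinusoid, warming offset, AR(1) daily noise), species presets with
    thermal performance curves, a YAML-configured command line workflow,
    and CSV/JSON input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    numDeriv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
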