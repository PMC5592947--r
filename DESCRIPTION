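Package: prfsim
Title: Single-Locus Wright-Fisher Forward Simulation Under the Poisson
    Random Field Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vectorized forward-in-time simulation of independent mutation
    frequency trajectories under the single-locus Wright-Fisher model with a
    Poisson Random Field mutation process. Supports multi-population
    demography with founding events, conservative migration, frequency- and
    time-dependent selection, dominance and inbreeding, binomial genetic
    drift, Poisson mutation influx, initialization in mutation-selection
    equilibrium by numerical integration of the expected frequency density,
    periodic compaction of lost and fixed mutations, and construction of
    population and sample site frequency spectra. Includes an exact
    finite-population Markov-chain reference for validation and a
    command-line interface driven by YAML scenario files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
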