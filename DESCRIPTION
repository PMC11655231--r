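Package: gastrosim
Title: Dynamic In Vitro Gastric Digestion Simulation and Emptying Kinetics for Infant Formulae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-balance simulation of a dynamic infant gastric simulator
    (continuous simulated-gastric-fluid secretion, periodic sieved emptying,
    curd retention, simplified pH titration), particle-size-distribution
    metrics (volume-weighted mean diameter d4,3, aggregation and coalescence
    indices), modified power-exponential (Elashoff) gastric-retention model
    fitting, dilution-corrected gel-densitometry kinetics, two-stage
    destabilization-versus-emptying correlation analysis, and a synthetic-data
    generator emulating casein-dominant, whey-dominant, and
    biopolymer-stabilized formula profiles so the whole pipeline is testable
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
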