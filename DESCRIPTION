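Package: turflag
Title: Individual-Based Simulation of Gridded Turf Plant Communities Under
    Climate Change
Version: 0.1.0
Authors@R: person("turflag", "developers", role = c("aut", "cre"),
    email = "maintainers@turflag.dev")
Description: Tools to model the demography of gridded grassland turfs under
    changing climate. Provides a data model for 1-m2 turfs subdivided into
    5x5 cm quadrants with ordinal canopy-cover records, Gaussian-kernel
    neighbourhood crowding, an algorithm that tracks demographic units
    between annual cover maps, climate- and density-dependent vital-rate
    models (survival, growth, recruitment), maximum a posteriori fitting of
    those models with parameter-recovery diagnostics, generators for
    gradual, stepwise and constant climate scenarios, an individual-based
    community simulator with burn-in quasi-equilibration and a lag-free
    counterfactual mode, and community summaries (Shannon diversity,
    Euclidean principal coordinates ordination, log cover ratios). A
    synthetic-data module generates complete miniature studies with known
    ground truth so the whole pipeline is testable without field data.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    numDeriv
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
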