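Package: myoregen
Title: Agent-Based Simulation of Skeletal Muscle Damage and Regeneration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Lattice agent-based model of skeletal muscle repair over a 28-day
    cycle following either mechanically localised (strain-seeded) or widespread
    (random) damage. Simulates fibril and extracellular-matrix pixels on a 2-D
    label grid, mobile neutrophil, macrophage (M1/M2), satellite-cell and
    fibroblast agents, and seven secreted-factor value layers (IL-10, IL-15,
    TNF-alpha, HGF, IL-6, IGF-1, TGF-beta) coupled through signed linear
    production equations and a diffusion-evaporation update with an edge sink.
    Includes a synthetic cross-section generator, strain-field import and
    synthesis, ensemble runners with mean/SD time series, derived recovery and
    peak statistics, condition comparison, and genetic-algorithm calibration of
    the 31 cytokine production coefficients against a fibroblast time course.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
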