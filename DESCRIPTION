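Package: phenoscape
Title: Bayesian Phenotypic Landscapes from Cellular Sensing and Proliferation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Maps coarse-grained cellular sensing statistics (intrinsic-extrinsic
    correlation, sensing bias, phenotypic signal-to-noise ratio) together with a
    Taylor-expanded proliferation profile onto an effective cubic phenotypic force,
    classifies the resulting landscape into canonical regimes (fixation, switch,
    critical switch, relaxation, explosion), computes barrier depths and analytic
    stationary densities, simulates the overdamped phenotypic Langevin dynamics,
    solves the associated Fokker-Planck and replicator equations, and sweeps
    sensing-bias by signal-to-noise phase diagrams at fixed correlation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
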