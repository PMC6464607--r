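Package: hairbundle
Title: Hair-Bundle Micromechanics and Tip-Link Tension Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for fluid-jet stimulation experiments on
    cochlear hair cells. Converts fluid-jet voltage commands into calibrated
    effective forces via a hydrodynamic model (Stokes drag on a prolate
    ellipsoid, jet velocity-profile integration), estimates hair-bundle
    stiffness and mechanical creep from force-step responses, decomposes
    stiffness into gating-spring and stereociliary-pivot contributions,
    infers the number of intact tip links from saturating transduction
    currents, and extracts resting and maximal tip-link tensions from
    iontophoresis traces. Includes the error-propagation machinery for
    products of means (Welch-Satterthwaite effective degrees of freedom),
    weighted tonotopic-gradient regression with slope comparison, and a
    synthetic-data generator that emulates every raw input so the full
    inference chain is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
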