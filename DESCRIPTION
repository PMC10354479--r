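Package: pterowing
Title: Ontogenetic Allometry, Wing Planforms and Flight Performance of Pterosaurs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multivariate (principal-component) estimation of growth-allometric
    coefficients from pterosaur skeletal measurement tables, with one-tailed
    bootstrap confidence bounds and allometry classification; power-law
    extrapolation of skeletal dimensions across a wingspan grid; geometric
    reconstruction of wing planforms with a cubic Bezier trailing edge (wing
    area, aspect ratio); body-mass scaling, wing loading and an actuator-disc
    flight-performance model (minimum power speed, flight efficiency, sinking
    rate, glide ratio); and pair-wise sign-flip permutation comparison of
    taxa. Includes a synthetic specimen-table generator with known allometric
    structure so that every stage of the pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
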