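Package: wormPosture
Title: Eigenworm Decomposition and Posture Dynamics of C. elegans Locomotion
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of undulatory locomotion in developing
    Caenorhabditis elegans from tracked segment-angle time series. Provides
    eigenworm (principal-component) decomposition of posture covariance,
    participation-ratio dimensionality with stage-wise pairwise testing,
    analytic-signal phase and phase-resolved trajectory speed of the
    locomotor cycle, two-dimensional amplitude density estimation, and a
    seedable synthetic undulation generator emitting the standard 11-column
    recording format, so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr,
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
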