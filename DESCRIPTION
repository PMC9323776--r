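Package: fiberGM
Title: Grey-System Modelling and NIR Chemometrics for Windmill Palm Fiber
    Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting the mechanical properties of windmill palm
    fiber from its lignocellulose composition. Implements the system-compliance
    method for extracting Young's modulus from single-fiber tensile tests, a
    multivariate grey model GM(1,N) linking cellulose, hemicellulose and lignin
    content to the modulus (initialization, accumulated generating operation,
    mean-generating sequence and least-squares coefficient estimation), and a
    near-infrared calibration protocol (vector normalization, Savitzky-Golay
    first derivative, standard normal variate, single-response partial least
    squares with cross-validation and paired t-test external validation).
    Ships the published data tables as fixtures with an automated
    internal-consistency report, and seedable simulators for NIR spectra,
    tensile compliance points and exactly-consistent grey systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
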