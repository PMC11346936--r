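Package: embryoflow
Title: Flow and Tissue Mechanics of the Embryonic Teleost Heart from
    Brightfield Micro-PIV
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers phase-averaged blood velocity fields from time-lapse
    brightfield microscopy of beating embryonic teleost hearts by ensemble
    phase-correlation micro particle image velocimetry (micro-PIV), and
    derives the downstream cardiac mechanics: relative pressure fields by
    omnidirectional line integration of the Stokes pressure gradient,
    pressure drops across the atrioventricular canal (AVC) and outflow
    tract (OFT), Green-Lagrange endocardial wall strain from an automated
    velocity-gradient segmentation, shear- and hematocrit-dependent blood
    viscosity (Walburn-Schneck), and the endocardial work (EW) metric that
    classifies the developmental stage of the heart. A synthetic phantom
    generator renders red-blood-corpuscle seeded image sequences over
    prescribed pulsatile flows with full ground truth, so every stage of
    the pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    Matrix,
    EBImage,
    fftwtools,
    tiff,
    pracma,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
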