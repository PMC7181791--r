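Package: microring
Title: Contractile Force Analysis for Cardiac Microring Tissues on
    Elastomeric Microcantilevers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis stack for 96-well cardiac microring (CaMiRi)
    contractility assays in which ring-shaped cardiac microtissues bend a
    pair of elastomeric microcantilevers. Converts post deflection to
    contractile force via Euler-Bernoulli beam theory or empirical
    force-displacement calibration; locates posts in low-magnification well
    images, scores focus, and builds kymographs from high-frame-rate videos;
    tracks the post edge at sub-pixel resolution and derives beat rate,
    contraction amplitude, contraction and relaxation velocities, and force;
    generates face-centred central composite designs and fits quadratic
    response surfaces with per-term ANOVA to locate optimal tissue
    formulations; summarizes drug screens as relative change in contraction
    amplitude with Mann-Whitney tests; and produces fully ground-truthed
    synthetic images, videos, and tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
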