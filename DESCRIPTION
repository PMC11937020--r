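Package: biophotonQC
Title: Biophoton-Based Quality Assessment of Medicinal Plant Leaves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ultra-weak photon emission of plant leaves as
    a quality indicator for herbal material. Fits the hyperbolic-cosecant
    (Gu) decay model to delayed-luminescence photon-count curves and derives
    the macroscopic parameters (initial intensity, decay time, window-averaged
    intensity), summarises spontaneous photon emission as background-corrected
    counts per second, normalises intensity measures by leaf mass and
    thickness, computes physiological stress indices (photosynthetic pigment
    contents, relative electrical conductivity, mitochondrial ROS production
    rate), calls minimum inhibitory concentrations from broth-microdilution
    plates, screens discriminative photon parameters with cross-validated
    LASSO, and relates parameters to quality endpoints through group tests
    and a Spearman correlation network. A synthetic-data module simulates
    Poisson photon-counting experiments and assay tables so the whole
    pipeline can be exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    minpack.lm,
    stats,
    utils,
    tools,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
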