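Package: stillmerge
Title: Merging and Error-Model Refinement for Serial Still-Image Crystallography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for merging partially recorded reflection intensities from
    serial (still-image) crystallography. Partial intensities are scaled to
    their full equivalents using per-image scale factors, Wilson B factors and
    partiality fractions; merged intensities and error estimates are produced
    under three protocols (unweighted mean with spread-based errors,
    inverse-variance weighting by photon-counting sigmas, and weighting by
    inflated sigmas from an SDFAC/SDB/SDADD error model). The error-model
    terms are initialized from a normal probability plot of leave-one-out
    normalized deviations and refined by gradient-based nonlinear least
    squares on binned root-mean-square deviations. Includes a synthetic
    still-diffraction generator with known ground truth, merging diagnostics
    (half-dataset correlation, resolution-binned signal-to-noise tables) and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'symmetry.R'
    'reflection-io.R'
    'grouping.R'
    'scaling.R'
    'merging.R'
    'ev11.R'
    'refine.R'
    'simulate.R'
    'diagnostics.R'
    'cli.R'
    'stillmerge-package.R'
RoxygenNote: 7.3.3
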