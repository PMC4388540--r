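Package: idaif
Title: Image-Derived Arterial Input Function Quantification for Dynamic PET
Version: 0.1.0
Authors@R: person("PUP", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of dynamic PET studies without
    arterial blood sampling. Implements the two-tissue compartment model and
    its closed-form solution, Logan graphical analysis with arterial input
    (distribution volume, VT) and with a reference region (distribution
    volume ratio, DVR), and an image-derived arterial input function (IDAIF)
    estimator that reconstructs the plasma input from an arterial
    region-of-interest time-activity curve using a dual one-tissue
    compartment tissue model with partial-volume recovery and spill-over
    correction. Includes constrained full kinetic fitting with fixed VT,
    vessel-mask construction utilities (PSF smoothing, volume-targeted
    thresholding, recovery-coefficient calculation), seeded synthetic-data
    generators (plasma input curves, regional tissue curves, a 4D vessel
    phantom), a minimal NIfTI-1 reader/writer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml, optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
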