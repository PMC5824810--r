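Package: memsculpt
Title: Quantitative Analysis of Membrane Sculpting by Curved Nanoscaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for reconstitution experiments in which curved
    scaffolds (BAR-domain mimics built from DNA origami) bind and tubulate
    giant unilamellar vesicles. Provides scaffold arc geometry and predicted
    tube diameters, Langmuir isotherm fitting of membrane-binding titrations,
    one-component two-dimensional FCS diffusion-model fitting with
    detection-volume calibration and absolute surface densities,
    Area-Difference-Elasticity bending energetics with an adhesion-versus-
    bending cost-benefit rule, per-vesicle morphology statistics with density
    thresholds, and a synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
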