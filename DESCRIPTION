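Package: synstereo
Title: Physical-Disector Stereology and Morphometry of Synapses in Serial-Section EM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for unbiased estimation of synapse number densities from
    serial-section electron microscopy using the physical disector with an
    unbiased counting frame, including full calibration of tissue deformation
    (embedding dilation, anisotropic ultramicrotomy deformation and section
    thickness error) back to the wet-tissue state. Provides log-normal synapse
    size statistics, minimum-bounding-sphere Feret diameters, a geometric model
    of synapses missed between consecutive cutting planes, jackknife and
    bootstrap estimators for the percentage of symmetric (inhibitory) synapses,
    random-intercept mixed-model group comparisons, and regional volume
    estimation from section outlines. A synthetic-tissue generator with known
    ground truth (Poisson-placed, log-normally sized, randomly oriented synapse
    proxies plus mitochondrial cylinders for thickness calibration) makes every
    stage of the pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    nortest,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
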