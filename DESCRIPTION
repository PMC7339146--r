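Package: somatlas
Title: Travelling-Wave Digit Mapping and Probabilistic Somatotopic Atlases
Version: 0.1.0
Authors@R:
    person("somatlas", "developers", email = "somatlas@example.org", role = c("aut", "cre"))
Description: Tools for phase-encoded (travelling-wave) functional MRI mapping of
    hand digit representations in primary somatosensory cortex and for building
    probabilistic group atlases from the resulting single-subject digit maps.
    Provides a synthetic-cohort generator with known ground truth, Fourier
    phase/coherence analysis with forward/backward run combination to cancel
    the haemodynamic delay, coherence-based statistical masking, equal-width
    phase binning into mutually exclusive digit regions, full and maximal
    probability map construction, and atlas validation metrics (blurring
    metric, central tendency with leave-one-out cross-validation, circular
    statistics including the Rayleigh V-test, ROI size comparisons and
    curvature variability). Maps are read and written as uncompressed NIfTI-1
    volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
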