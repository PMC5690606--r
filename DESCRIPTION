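Package: glassbold
Title: Developmental fMRI Analysis of Glass-Pattern BOLD Responses
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for charting the functional development of visual cortex
    from longitudinal block-design BOLD fMRI. Provides Glass-pattern stimulus
    and schedule generation, a synthetic longitudinal BOLD generator with
    known ground truth, per-voxel linear detrending, two-predictor GLM
    mapping with FDR and within-VOI Bonferroni thresholding, a spectral
    signal-to-noise metric at the stimulus alternation frequency, rank-ordered
    multivoxel pattern classification with a binomial chance model, the
    d-prime sensitivity index with bootstrap resampling, and constrained
    Naka-Rushton developmental trajectory fits with criterion-age inversion
    and bootstrap comparisons between visual areas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
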