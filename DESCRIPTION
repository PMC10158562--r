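Package: erpmicro
Title: Topographic and Microstate Analysis of Picture-Naming ERPs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An analysis pipeline for developmental picture-naming
    event-related potentials (ERPs): preprocessing of stimulus- and
    response-locked epochs (zero-phase Butterworth filtering, average
    reference, baseline correction, amplitude-based artifact rejection,
    spherical-spline interpolation of bad electrodes), reference-free
    topographic statistics (global field power, global map dissimilarity,
    topographic consistency tests, topographic ANOVA by randomization),
    sampling-point-wise factorial ANOVA with temporal and spatial extent
    criteria, microstate segmentation by temporal atomize-and-agglomerate
    hierarchical clustering (TAAHC) with model selection and back-fitting
    of template maps to individual ERPs (presence, explained variance,
    duration), and reaction-time-based removal of the overlap between
    stimulus- and response-locked ERPs. Includes a synthetic-data
    generator that plants known microstate structure, latency shifts and
    amplitude scaling so that every stage of the pipeline can be verified
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
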