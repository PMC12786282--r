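Package: plasmoKAN
Title: Nanoplasmonic Biosensing Simulation and Kolmogorov-Arnold Network
    Classification of Reflectance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forward modeling of gold-nanohole metasurface reflectance
    spectra under small-extracellular-vesicle binding (surface plasmon
    polariton and Wood-Rayleigh anomaly resonances, Langmuir adsorption,
    effective-index mixing, Beer-Lambert intensity loss), synthetic
    case-control cohort generation with pre-/post-detection spectrum pairs,
    conventional biosensing readouts (refractometric, spectroscopic and
    nanoplasmonic-loading-effect features with four-mode fusion), and a
    full-spectrum Kolmogorov-Arnold network classifier with positional
    encoding and multi-head self-attention, evaluated with ROC and
    precision-recall diagnostics, dual-marker fusion and permutation
    importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    splines,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
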