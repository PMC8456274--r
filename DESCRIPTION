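Package: smpdx
Title: Serum Metabolic Profile Diagnostics with a Deep Spectral Stabilizer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for laser desorption/ionization
    mass-spectrometry (LDI-MS) based metabolic diagnosis. Generates synthetic
    serum spectra with laser-shot-dependent acquisition noise, extracts serum
    metabolic profiles (local-maximum peak picking, signal-to-noise filtering,
    m/z alignment), trains a generative-adversarial "deep stabilizer" that maps
    low-shot spectra to high-shot-equivalent spectra, fits sparse (elastic net)
    and OPLS-DA classifiers with cross-validation and permutation testing,
    screens biomarkers under multiple restrictions, and evaluates diagnostic
    reproducibility through the diagnosis-variation-characteristic (MK) surface
    and its volume under surface (VUS).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    mzR,
    pROC
Config/testthat/edition: 3
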