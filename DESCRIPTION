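Package: vagalfib
Title: Vagal Modulation of Atrial Fibrillatory Frequency in 2D Tissue Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the effect of spatiotemporally varying acetylcholine (ACh)
    release on the fibrillatory frequency of reentrant activity in two-dimensional
    human atrial tissue. Includes the Courtemanche-Ramirez-Nattel atrial myocyte
    model with persistent-AF electrical remodeling and an ACh-activated potassium
    current, MacCannell active fibroblasts for diffuse fibrosis, an anisotropic
    monodomain finite-difference solver with conduction-velocity calibration,
    generators of diffuse and ganglionated-plexus ("octopus") ACh release
    patterns, and the f-wave frequency analysis pipeline (instantaneous-frequency
    extraction, peak-conditioned spectral selection, spatial trimmed averaging,
    respiration-band Hilbert-envelope modulation magnitude, and Spearman
    correlation against the ACh waveform), together with pseudo-ECG dominant
    frequency cross-checks and synthetic fixtures for fast testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
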