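Package: hbci
Title: Hybrid EEG-NIRS Brain-Computer Interface Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing, feature extraction, classification and
    evaluation for hybrid EEG-NIRS brain-computer interfaces based on short
    (5 s) mental-arithmetic and word-chain trials. Implements filter-bank
    common spatial patterns with log-variance features, windowed hemodynamic
    mean/slope features after modified Beer-Lambert law conversion,
    shrinkage-regularized linear discriminant analysis with analytic
    Ledoit-Wolf shrinkage, two-layer meta-classification fusing EEG and NIRS
    decisions, offline repeated cross-validation and session-wise
    pseudo-online evaluation, information transfer rates, event-related
    spectral perturbation maps, and a deterministic synthetic multimodal
    recording generator so the whole pipeline is testable without access to
    laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
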