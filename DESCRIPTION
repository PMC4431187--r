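Package: nirpls
Title: NIR Multivariate Calibration for Extraction-Process Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric calibration pipeline for online near-infrared (NIR)
    monitoring of herbal extraction processes. Implements NIPALS partial least
    squares (PLS1) regression with leave-one-out PRESS-based latent-variable
    selection, Kennard-Stone sample-set partitioning, a standard spectral
    preprocessing menu (Savitzky-Golay smoothing and derivatives, SNV, MSC,
    vector normalization), synergy-interval PLS (SiPLS) and moving-window PLS
    (MWPLS) variable selection, and bootstrap-aggregated (bagging) PLS
    ensembles. Ships a synthetic-data generator that emulates a three-batch
    pilot-scale extraction experiment with known ground truth, so the whole
    pipeline is testable end to end without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
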