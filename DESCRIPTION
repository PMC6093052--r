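Package: nirflav
Title: Near-Infrared Calibration of Total Flavonoid Content and
    Antioxidant Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A chemometrics pipeline for calibrating total flavonoid
    content (mg rutin equivalents per g dry weight) and total antioxidant
    activity (mM Trolox equivalents per g dry weight) of plant material
    against near-infrared diffuse-reflectance spectra. Implements spectral
    preprocessing (standard normal variate, multiplicative scatter
    correction, moving-window smoothing, Savitzky-Golay derivatives),
    PCA/Mahalanobis-distance/leverage outlier screening, Kennard-Stone
    sample partitioning, NIPALS partial least squares regression with
    10-fold cross-validated factor selection, the usual RMSECV/RMSEC/RMSEP
    and correlation metrics, wet-chemistry assay arithmetic (rutin
    calibration line, DPPH scavenging, Trolox equivalents), and a seeded
    synthetic spectra generator for end-to-end testing when raw spectra are
    unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
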