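Package: hyperseed
Title: Kernel-Based Seed Viability Classification from NIR Hyperspectral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end chemometric pipeline for scoring seed viability from
    line-scan short-wave-infrared hyperspectral images. Provides ENVI cube
    input/output, white/dark reflectance calibration, scan-line baseline
    correction, per-spectrum pretreatments (SNV, max/mean/range normalization,
    Savitzky-Golay smoothing), single-band seed segmentation, a NIPALS PLS-DA
    classifier with cross-validated latent-variable selection, variable
    importance in projection (VIP) waveband selection, and kernel-level (whole
    seed) classification by per-seed pixel detection rates with ROC-based
    optimal-threshold selection. A synthetic line-scan scene generator with
    known ground truth supports validation without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    signal,
    png,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
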