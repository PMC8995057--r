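Package: nanomef
Title: Morphometry and Assay Analytics for Plasmonic Nanoisland Substrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the morphology of silver nanoisland
    substrates used in metal-enhanced fluorescence (MEF) and for the
    statistics of the enhanced fluoroimmunoassays (eFIA) built on them.
    Implements SEM-image gap-distance morphometry (Otsu binarization,
    clean/majority cleanup, topology-preserving gap skeletonization,
    Euclidean distance transform, the 2x gap-distance statistic and its
    gamma-distribution summary), surface-coverage and continuity-regime
    classification, fluorescence enhancement-factor analytics with
    correlation-matrix PCA and Kaiser-Guttman retention, and the assay
    statistics chain: saturating-exponential calibration, blank-based
    limit of detection, intra/inter-assay coefficients of variation, ROC
    analysis with Youden-optimal cutoff, and Bland-Altman agreement.
    A stochastic island-growth simulator generates morphologies across
    the discrete / semi-continuous / continuous regimes together with
    synthetic calibration and cohort data, so the full pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    fitdistrplus,
    igraph,
    jsonlite,
    minpack.lm,
    optparse,
    png,
    stats,
    tiff,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
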