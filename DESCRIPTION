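Package: vsmcq
Title: Quantification Pipelines for Single-Cell AFM Mechanics and Smooth
    Muscle Signaling Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify vascular smooth muscle cell mechanics and
    signaling from standard laboratory readouts. Implements an atomic force
    microscopy (AFM) force-curve analysis for cylindrical (flat-punch)
    indenters: baseline-noise estimation, noise-threshold contact-point
    detection, a candidate-grid search around the experimental contact point
    with iterative window-growing Hertz fits stopped by a root-mean-square
    deviation rule, cell-height estimation from paired substrate/cell contact
    points, and rigidity time-course normalization. Also provides Fura-2
    ratiometric calcium calibration and phase-wise response metrics,
    rolling-ball style background removal with thresholded integrated
    density for fluorescence micrographs, TNBSA free-amine percent
    modification against a glycine standard curve, multi-reference-gene
    relative qPCR quantification, loading-control-normalized immunoblot
    quantification, and a normality-gated group-comparison front end. A
    synthetic-data module generates inputs with known ground truth for every
    stage so the whole pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    multcomp,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
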