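Package: cbppg
Title: Automated Region-of-Interest Selection and Tracking for
    Camera-Based Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Anatomy-free selection and tracking of skin regions of
    interest (ROIs) in synchronized RGB and near-infrared (NIR) video for
    camera-based photoplethysmography (cbPPG). A histogram-based Bayesian
    skin classifier initializes a two-phase level-set segmentation that
    maximizes regional homogeneity of intensity and texture; the RGB ROI
    is transferred to the NIR stream by mean-adjusted block matching and
    refined by a second segmentation. ROIs are tracked frame-to-frame
    with artifact monitoring and automatic redetection. Downstream tools
    extract per-channel plethysmographic signals, estimate heart rate
    per 10-second segment via zero-padded FFT, compute a spectral
    signal-to-noise ratio, and summarize detection rates across subjects.
    A scripted scene generator produces synthetic RGB+NIR video pairs
    with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
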