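Package: motrace
Title: Single-Molecule Motility Analysis for Processive Cellulases from
    Optical-Tweezers Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for bead-position records from surface-coupled
    optical-tweezers assays of processive cellulases. Provides a synthetic
    trace generator with known ground truth (Markov state switching between
    forward, backward and paused motility, instrumental drift, Brownian
    position noise, and abrupt nanometre-scale displacements), preprocessing
    (decimation, exponentially weighted moving average, downsampling),
    fiducial-marker drift correction by sub-pixel cross-correlation tracking,
    automated constant-velocity changepoint segmentation with triplicate
    penalty jitter, duration-weighted exponential velocity fits,
    left-truncated single- and double-exponential dwell-time fits by
    expectation-maximization, control-derived pause thresholds, jump
    detection, bootstrap two-sample mean tests, and force-binned velocity
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
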