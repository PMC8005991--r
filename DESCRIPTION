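Package: opposcreen
Title: Thumb-Reaching Kinematics and Autoencoder Screening for Carpal
    Tunnel Syndrome
Version: 0.1.0
Author: Package Author
Maintainer: Package Author <author@example.com>
Description: Tools for screening carpal tunnel syndrome (CTS) from
    smartphone thumb-reaching trajectories. Timestamped 2-D thumb
    positions recorded while reaching targets in 12 directions on a
    2-cm circle are summarised into per-direction kinematics, encoded
    as fixed-size 12 x 50 grayscale feature images of normalized
    distance-to-center over time, and scored by the reconstruction
    error of an autoencoder trained on healthy hands only. Includes
    ROC/AUC evaluation with Youden-optimal cutoffs, a per-direction
    window sub-model sweep, and a minimum-jerk synthetic cohort
    simulator so the full pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
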