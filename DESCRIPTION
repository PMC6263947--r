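Package: eecgnet
Title: ECG Biometric Identification with PCA Filter-Bank Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies individuals from electrocardiogram (ECG) recordings.
    Raw multi-lead ECG is reduced to a per-subject averaged heartbeat and
    reshaped into a small image; features are extracted with a two-stage
    principal-component filter-bank network (patch sliding, patch-mean
    removal, eigenvector filters, convolution, binary hashing, block-wise
    histograms) and classified with a multi-class linear support vector
    machine. Includes a reproducible synthetic ECG cohort generator with
    controllable PQRST morphology and noise, eigen-PCA and extreme learning
    machine baselines, signal-fidelity metrics (PRD, PRDN, RMS, SNR,
    compression ratio), a parameter sweep harness, and readers for WFDB-style
    and delimited signal files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    MASS,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tidyr,
    withr
Config/testthat/edition: 3
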