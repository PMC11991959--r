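Package: ripsleep
Title: Sleep-State and Arousal Scoring from Respiratory Inductance
    Plethysmography Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores sleep states (Wake, NREM, REM) at 30-second epoch
    resolution and detects arousals at 1-second resolution from two-belt
    respiratory inductance plethysmography (RIP) recordings alone, with no
    electroencephalography. Provides a seeded synthetic overnight RIP
    generator with known hypnogram, arousal and respiratory-event ground
    truth; adaptive baseline removal and context-window assembly; a
    multi-task dilated temporal convolutional network (trained with AdamW,
    batch normalization and spatial dropout) emitting per-epoch
    hypnodensity and per-second arousal probabilities; rule-based event
    scoring (3-second threshold rule, hypnogram smoothing, total sleep
    time and arousal index); and a complete scoring-agreement framework
    (confusion matrices, one-vs-rest metrics, Cohen's kappa, bootstrap
    confidence intervals, Bland-Altman limits of agreement, intraclass
    correlation, apnea-hypopnea-index stratification). Reads and writes
    EDF signal files and plain-text annotation sidecars, and exposes a
    command-line interface covering the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    optparse,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
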