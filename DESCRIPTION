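Package: artstiff
Title: Beat-by-Beat Arterial Stiffness Estimation from Blood Pressure and
    Photoplethysmogram Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the peripheral arterial stiffness index beta for every
    heartbeat from simultaneously recorded continuous blood pressure and
    photoplethysmogram (PPG) waveforms, using a log-linearized arterial
    viscoelastic model fitted by a two-step per-beat least-squares procedure
    (inertia and viscosity first, then the stiffness exponent on the
    log-residual elastic pressure above mean blood pressure). Includes
    QRS-triggered beat segmentation, a reconstruction R-squared quality gate,
    normalization of beta against a no-stimulation baseline, sigmoid mapping
    of normalized stiffness to an estimated numeric pain rating (eNRS), and a
    forward simulator with a configurable electrocutaneous stimulation
    protocol so the full analysis chain can be validated by parameter
    recovery on synthetic records with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
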