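Package: respmsna
Title: Respiratory Modulation of Muscle Sympathetic Nerve Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for synchronized ECG, arterial pressure,
    respiration and integrated muscle sympathetic nerve activity (MSNA)
    recordings. Detects cardiac and respiratory landmarks, extracts
    beat-to-beat hemodynamics, detects pulse-synchronous MSNA bursts and
    latency-aligns the neurogram, quantifies respiratory sympathetic
    modulation over composite inspiratory/expiratory phases, estimates
    spontaneous sympathetic baroreflex sensitivity by weighted regression
    over diastolic-pressure bins, measures respiratory sinus arrhythmia and
    Traube-Hering wave amplitude per breath with their lagged coupling to
    respiratory-modulated MSNA, and runs cohort-level statistics
    (mixed-model ANOVA, group comparisons, correlations). Includes a
    synthetic-signal generator with known ground truth so every stage is
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
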