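Package: ftdqeeg
Title: Frontal-Temporal Spectral Power Ratio Markers for Frontotemporal
    Dementia from Resting-State EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative EEG analysis of inter- and intra-lobar spectral
    power ratios between the frontal and temporal lobes as diagnostic
    markers of frontotemporal dementia (FTD). Computes absolute band
    powers (delta, theta, alpha, beta, gamma) from resting-state 10-20
    recordings under several Welch/FFT parameterizations and referencing
    schemes (average and REST infinity reference), forms the full set of
    65 lobar power ratios, screens them with Mann-Whitney U tests under
    Benjamini-Hochberg correction, and quantifies diagnostic accuracy
    with DeLong ROC inference, interpolated precision-recall curves with
    logit-method intervals, Youden-index cutoffs with bootstrap
    confidence intervals, prevalence-standardized predictive values, and
    stepwise logistic regression. Includes a synthetic resting-state
    cohort generator with configurable lobe-by-band group effects, plus
    EDF/EEGLAB-SET/BIDS readers, so the full pipeline runs end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    ggplot2
Config/testthat/edition: 3
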