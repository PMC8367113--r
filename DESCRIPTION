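Package: nbdcdep
Title: Depressive Symptom Severity from Nearby Bluetooth Device Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline linking hourly nearby-Bluetooth-device-count
    (NBDC) sequences recorded by mobile phones to depressive symptom severity
    measured with the 8-item Patient Health Questionnaire (PHQ-8). Provides a
    synthetic-cohort generator with circadian structure and latent-severity
    coupling, preprocessing with valid-day and valid-interval inclusion rules
    and linear interpolation of missing hours, extraction of 49 Bluetooth
    features (second-order statistics, multiscale sample entropy at scales
    1-24, and periodogram band powers, band fractions and spectral entropies),
    pairwise linear mixed-effects association screening with Benjamini-Hochberg
    correction and a nested-model likelihood-ratio ladder, and hierarchical
    Bayesian prediction of PHQ-8 scores evaluated under leave-all-out and
    leave-one-out time-series cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    rjags,
    optparse
Config/testthat/edition: 3
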