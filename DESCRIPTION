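Package: emaroam
Title: Daily Affect, Mobility and Early Adolescent Alcohol Use from
    Ecological Momentary Assessment and GPS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for studying day-level predictors of early adolescent
    alcohol use from smartphone-based ecological momentary assessment (EMA)
    and per-minute GPS trajectories. Computes daily roaming entropy and
    contact episodes with categorized alcohol trigger points from raw GPS
    fixes, scores and aggregates EMA prompts to participant-days with a
    day-shifted morning alcohol report, applies compliance and prompt-count
    filters, and fits a binomial random-intercept multilevel model with
    Nakagawa pseudo-R-squared, null-model deviance comparison and a
    prompt-threshold sensitivity series. A calibrated synthetic-data
    generator emulates cohort, EMA, GPS and point-of-interest inputs so the
    full pipeline and parameter recovery can be exercised without access to
    raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    geosphere,
    glmmTMB,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
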