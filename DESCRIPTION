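Package: critwindow
Title: Open and Closed States of the Social Reward Learning Critical Period
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative framework for deciding whether the developmental
    critical period for social reward learning is in an "open" or "closed"
    state. Converts social conditioned place preference (sCPP) zone-occupancy
    data into normalized and subtracted preference scores with the standard
    pre-conditioning exclusion rules, fits the developmental trajectory of
    normalized social preference with natural-spline (and linear, B-spline,
    loess) regression selected by leave-one-out cross-validation, and
    classifies new cohorts as open or closed via a nested-model mean-shift
    test against the fitted closed-state curve. Also provides miniature EPSC
    event detection with amplitude and rise-time filters and per-cell
    frequency/amplitude/inter-event-interval summaries, a battery of
    hypothesis tests (t, F, Levene, one-way ANOVA with multiple comparisons,
    multivariate likelihood-ratio test, Benjamini-Hochberg FDR), a
    likelihood-ratio differential-expression contrast of open- versus
    closed-state conditions with a batch covariate, and seeded synthetic-data
    generators that emulate the statistical structure of all three data
    modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    splines,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
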