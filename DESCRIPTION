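Package: sleepsca
Title: Specification Curve Analysis of Adolescent Sleep and Digital Engagement
Version: 0.1.0
Authors@R:
    person("Jonas", "Calder", email = "jcalder@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for specification curve (multiverse) analysis of
    the association between digital technology engagement and adolescent sleep,
    modelled on large UK cohort questionnaire and time-use-diary instruments.
    Includes a calibrated synthetic cohort generator (latent-threshold ordinal
    items, 144-slot time-use diaries with configurable true effects), derived
    sleep and technology measures, enumeration of the full grid of defensible
    analytical specifications, standardized OLS fitting with listwise deletion,
    percentile bootstrap inference over the whole curve, summary statistics,
    and specification-curve dashboard plots with a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    grid,
    ggplot2,
    rlang,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
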