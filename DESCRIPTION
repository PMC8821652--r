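Package: prescore
Title: Parameter Response Efficacy Scores for Predicting Long-Term Treatment
    Effects from Short-Term Risk Marker Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates short-term (baseline to month 6) changes in multiple
    cardiovascular and kidney risk markers observed in a two-arm clinical
    trial into a predicted long-term relative risk reduction, by pushing the
    marker changes through a Cox proportional hazards risk model fitted on an
    independent background cohort.  Provides synthetic cohort generators
    calibrated to published population summaries, predictive mean matching
    multiple imputation, parametric coefficient-resampling confidence
    intervals, single-marker attribution, subgroup scoring, and
    responder-enrichment simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    survival,
    tibble,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
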