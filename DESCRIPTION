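Package: arurhythm
Title: Activity Rhythms and Departure Detection from Automated Radio Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts per-minute signal-strength logs from automated radio
    telemetry receivers (ARUs) into activity time series for free-living
    birds.  Provides threshold calibration from static reference tags,
    ternary active/inactive/unknown classification with quality filtering,
    detection of nocturnal migratory departure events, civil-twilight
    computation from solar geometry, 30-minute activity budgets aligned to
    departure, and a penalized-spline binomial generalized additive mixed
    model (with observation-level random effects) plus restricted
    maximum-likelihood linear mixed models for comparing circadian activity
    rhythms between migrant and resident phenotypes.  A synthetic ARU data
    generator with known ground truth makes the full pipeline testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    lubridate,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    mgcv,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
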