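Package: snackdex
Title: Snacking Behaviour Analysis from Timed Food Diaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for chrono-nutrition analysis of timed food-diary data:
    aggregation of logged intake into eating occasions by a 30-minute gap
    rule, snack identification and cleaning filters, per-participant snack
    frequency, energy share, a quantile-based Snack Diet Index, NOVA
    processing-level energy shares, temporal snacking patterns and
    late-evening snacking, postprandial incremental area under the curve and
    HOMA-IR derivations, covariate-adjusted association models with false
    discovery rate control, and a twin-aware random-forest framework for
    relating snacking traits to species-level gut microbiome composition,
    including confounder-matched subset resampling. A seeded synthetic-cohort
    generator with planted effects makes every stage testable without access
    to managed-access cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    ranger,
    pROC,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
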