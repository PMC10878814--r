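Package: selmix
Title: Selection-Model Mixture Meta-Analysis of Intervention Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood fitting of K-component normal-mixture
    random-effects meta-analysis models with optional one-parameter
    step-function selection (reporting-bias) components, BIC-based model
    comparison and Bayesian model averaging over selection mechanisms,
    and a synthetic trial generator with a configurable suppression
    process so the whole pipeline can be exercised and validated without
    external data. Designed for effect-size tables in the layout of
    large nudge-unit trial archives (one estimated treatment effect in
    percentage points per row, with its standard error and trial/domain
    labels).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
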