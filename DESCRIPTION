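Package: grmbank
Title: Graded Response Model Toolkit for Patient-Reported Outcome Item Banks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Psychometric evaluation of polytomous patient-reported outcome
    item banks under Samejima's graded response model (GRM). Provides
    classical reliability statistics (Cronbach's alpha, item-rest
    correlations), checks of the three GRM preconditions
    (unidimensionality via KMO/Bartlett/eigenvalue ratio, local
    independence via Yen's Q3 residual correlations, monotonicity via
    rest-score conditional means), marginal-maximum-likelihood EM
    calibration with item screening rules, item/test information and
    operating characteristic curves, EAP trait scoring,
    limited-information model fit indices, and uniform/non-uniform
    differential item functioning by nested ordinal logistic regressions
    with McFadden pseudo-R2 effect-size gating. Ships the calibrated
    23-item Chinese PROMIS-Cancer-Anxiety bank as a worked fixture and a
    synthetic-response generator for study-shaped simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
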