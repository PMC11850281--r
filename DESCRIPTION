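Package: dietpanel
Title: Farm Production Diversity and Household Dietary Diversity in Panel Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing how farm production diversity relates to
    household dietary diversity in multi-country household panel surveys.
    Provides a validated long-format panel container with CSV interchange,
    a synthetic LSMS-like panel generator with nested geography and
    household-level unobserved heterogeneity, household dietary diversity
    scores (total and by food source), farm production diversity metrics
    (species and food groups), food-group production diversity aggregated
    to village, town and district scales, correlated random effects
    (Mundlak), fixed effects and Poisson panel estimators with
    cluster-robust covariance, interaction marginal effects,
    inverse-probability attrition weights, and pipelines that reproduce
    descriptive and regression batteries end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
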