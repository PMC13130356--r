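Package: kdmcohort
Title: Klemera-Doubal Biological Age, Dietary Indices, and Design-Based
    Logistic Regression for Survey Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for population analyses of biological aging on complex
    survey cohorts: the Klemera-Doubal method (KDM) biological-age estimator
    and its residual-based age acceleration; the dietary index for gut
    microbiota (DI-GM) and the composite dietary antioxidant index (CDAI);
    survey-weighted logistic regression with Taylor-linearized
    stratified-cluster variance; and a synthetic NHANES-like cohort
    generator with planted effect sizes so every analysis stage can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
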