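Package: panelgvar
Title: Panel Graphical Vector Autoregression Networks for Ordinal Symptom Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of within-person temporal and contemporaneous symptom
    networks and a between-person network from few-wave ordinal questionnaire
    panels, using a random-intercept graphical vector-autoregression (GVAR)
    model fitted by full-information maximum likelihood. Includes the
    surrounding study workflow: long/wide panel readers, item variance
    screening, linear detrending and pooled standardization, descriptive
    statistics (item moments, scale totals, Cronbach's alpha, cut-off
    prevalence, attrition comparisons), Wald-test pruning and BIC-guided
    model search, SEM fit indices, strength centrality, case-drop subsampling
    stability analysis, and a calibrated latent-Gaussian synthetic-data
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
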