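Package: meansits
Title: Interrupted Time-Series Evaluation of Means-Restriction Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quasi-experimental evaluation of means-restriction
    public-health interventions from method-specific death counts. Provides a
    synthetic multi-site count-series generator with known ground truth,
    ICD-10 method classification and annualized rate tables, nonparametric
    local-polynomial estimation of the suicide intensity function with a
    change-point assessment at the intervention date, seasonal B-spline
    Poisson and negative-binomial regression with AIC knot selection,
    overdispersion and probability-integral-transform diagnostics, and a
    counterfactual simulation estimating the number of lives saved by the
    intervention.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    splines,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
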