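Package: gehroc
Title: Global Electrical Heterogeneity Metrics and Dynamic Predictive
    Accuracy for Competing Mortality Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes global electrical heterogeneity (GEH)
    vectorcardiographic metrics (spatial QRS-T angle, spatial ventricular
    gradient direction and magnitude, SAI QRST) from 12-lead ECGs via the
    Kors transform and a time-coherent median beat, and evaluates the
    dynamic (horizon-dependent) predictive accuracy of continuous markers
    for competing mortality outcomes in censored longitudinal cohorts:
    time-dependent ROC(t) AUC with the nearest-neighbour bivariate
    survival estimator, five-partition internal validation with bootstrap
    confidence intervals, analytic expected CI width for an AUC at a
    given event count, and risk reclassification (IDI and NRI) on top of
    a clinical logistic model.  A synthetic-data module generates 12-lead
    ECGs with known vector geometry and competing-risk cohorts with known
    marker-hazard links so the whole pipeline is testable without access
    to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
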