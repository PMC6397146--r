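Package: seasdhr
Title: Time-Varying Seasonal Analysis of Irregularly Sampled Stream Monitoring Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies recurring seasonality in irregularly
    sampled river-monitoring series. Implements dynamic harmonic regression
    with stochastic time-varying coefficients estimated by Kalman filtering
    and fixed-interval smoothing in continuous time, so sampling gaps of any
    length are handled through gap-dependent state transitions; includes
    maximum-likelihood estimation of noise variance ratios, pointwise
    confidence bands and analysis-of-variance style fit statistics.
    Companion tools compute diatom-based water-quality indices and
    Ecological Quality Ratios from valve-count matrices, aggregate
    high-frequency sensor records over antecedent windows, ordinate species
    matrices by principal component analysis with passive projection of
    environmental variables, and simulate synthetic monitoring datasets with
    known ground truth for method evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
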