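Package: tadanet
Title: Multinetwork Time-of-Acquisition Diffusion Analysis on Dynamic Animal
    Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring social-learning pathways from automated
    tracking data on wild birds. Builds gathering events from RFID feeder
    detections via Gaussian-mixture clustering, computes simple-ratio
    association indices split into vertical (parent-offspring), oblique
    (nonparental adult), sibling and nonsibling-peer layers, and fits
    multinetwork time-of-acquisition diffusion models (TADA, the survival
    variant of network-based diffusion analysis) with constant or Weibull
    baselines, AICc model averaging, profile-likelihood confidence intervals
    and per-event learning-pathway decomposition. Includes covariate builders
    and estimators for parental-exposure and side-choice (conformity versus
    personal information) regressions, and a synthetic-data generator with
    known transmission ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mclust,
    lme4,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
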