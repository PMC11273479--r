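Package: poolsdm
Title: Spatial Distribution Modelling of Pooled Species from Trawl Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Presence-absence species distribution modelling for closely
    related species whose catches are merged in fishery statistics. Fits
    binomial generalized linear mixed models with natural-spline covariate
    smooths and Matern (SPDE) Gaussian Markov random fields estimated by a
    Laplace-approximated marginal likelihood; provides AIC stepwise covariate
    selection, k-fold and leave-future-out cross-validation, AUC/MCC/Brier
    evaluation, a comparison of data-pool versus prediction-pool strategies
    for merged species, gridded habitat projection under climate scenarios,
    trawl-survey CPUE summaries, and a synthetic survey generator for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Matrix, methods, splines, stats, utils
Suggests: testthat (>= 3.0.0), geosphere, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
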