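Package: ascatime
Title: ANOVA Simultaneous Component Analysis with Continuous-Time Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multivariate analysis of frequently sampled longitudinal
    cross-over studies (e.g. postprandial metabolomics time courses).
    Each response is modelled by a linear mixed model with a polynomial or
    natural-cubic-spline expansion of numeric time and sum-coded
    time-by-treatment interactions, estimated by REML. The multivariate
    response matrix is decomposed into additive fixed- and random-effect
    matrices (baseline, time, time-treatment interaction), each summarised
    by centered PCA via the singular value decomposition with standardized
    scores and loadings. Non-parametric subject-level bootstrapping with
    orthogonal Procrustes alignment provides percentile confidence
    intervals for scores and loadings. A simulator with known encoded
    effects supports verification and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    splines,
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
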