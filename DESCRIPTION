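Package: stressphen
Title: Stress Phenotyping of Group-Housed Fish from Behavior, Waterborne
    Cortisol and Brain Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for tank-level stress phenotyping of small
    gregarious fish. Converts overhead video trajectories into
    body-length-normalized swimming activity and thigmotaxis, models the
    post-stressor freeze-and-recovery episode with a five-parameter Weibull
    dip curve fitted by bounded nonlinear least squares, extracts freezing
    intensity and time to freeze in closed form, quantifies waterborne
    cortisol from a four-parameter logistic immunoassay standard curve with
    parallelism and coefficient-of-variation quality control, normalizes
    qPCR expression by the geometric mean of housekeeping genes, and
    compares four candidate linear mixed models (additive or interaction
    fixed effects crossed with random intercept or random slope) by AIC for
    each response. Includes seeded simulators for trajectories, cortisol
    time courses and qPCR tables so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    lmerTest,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
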