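Package: surromet
Title: Trial-Level Surrogacy Evaluation from Reconstructed Survival Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating trial-level surrogate endpoints in oncology
    meta-analyses of time-to-event outcomes. Reconstructs pseudo
    individual-patient data from digitized Kaplan-Meier coordinates and
    numbers-at-risk tables (Guyot algorithm), computes survival endpoints
    (quantiles, restricted mean survival time, milestone rates), pools
    survival curves across trials by conditional-survival random-effects
    meta-analysis with DerSimonian-Laird heterogeneity, tests proportionality
    of hazards between progression-free and overall survival with Schoenfeld
    residual diagnostics and time-dependent Cox models, and quantifies
    surrogacy by sample-size-weighted meta-regression R-squared with subgroup
    interaction tests. Includes a synthetic multi-arm trial generator with
    coupled progression-free and overall survival, controllable trial-level
    surrogacy correlation, and an emulated curve-digitization step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    metafor,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
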