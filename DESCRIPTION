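Package: attncpm
Title: Task-Connectome Prediction of Sustained Attention and Longitudinal
    Substance-Use Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, simulation-backed pipeline linking stop-signal-task
    behaviour to task-fMRI connectomes and longitudinal substance use.
    Computes the intra-individual coefficient of variation (ICV) of go
    reaction times with the associated quality-control exclusions; builds
    ROI-to-ROI generalized psychophysiological interaction (gPPI)
    connectivity matrices from task time series; runs connectome-based
    predictive modelling (CPM) with k-fold and leave-site-out
    cross-validation, consensus edge sets, permutation significance and
    cross-cohort model transfer; reduces substance-use items to factor
    scores via principal-component factor analysis with varimax rotation;
    and fits a three-wave bivariate latent change score model by maximum
    likelihood with standard fit indices. A synthetic-data module generates
    every input the pipeline consumes, with recorded ground truth for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
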