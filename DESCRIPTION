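Package: dynfc
Title: Trial-Resolved Dynamic Functional Connectivity for Fear Extinction Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates trial-resolved task functional connectivity from
    beta series using a jackknife (leave-one-trial-out) procedure, summarises
    it into time-block matrices and early-to-late connectivity change (delta FC),
    performs family-wise-error-controlled group inference on connectome edges
    with the Network-Based Statistic, maps significant components onto canonical
    brain networks, relates learning-phase connectivity change to recall-phase
    signals with max-statistic permutation control, and links connectivity
    change to clinical measures through permutation-validated, cross-validated
    canonical correlation analysis. Ships a synthetic cohort generator with
    planted, group-specific connectivity dynamics so that every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'utils.R'
    'boldGlm.R'
    'networkMaps.R'
    'ccaClinical.R'
    'syntheticCohort.R'
    'cohortIO.R'
    'groupNBS.R'
    'crossPhase.R'
    'dynfc-package.R'
    'fcDynamics.R'
    'jackknife.R'
    'pipeline.R'
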