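Package: rsnflow
Title: Effective Connectivity Among Resting-State Networks via Group ICA
    and Conditional Granger Causality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying directed information flow between
    resting-state brain networks and its relation to behavioral traits.
    Includes a synthetic resting-state cohort generator with known network
    couplings; minimum-description-length estimation of the number of latent
    components; temporal-concatenation group spatial independent component
    analysis (FastICA) with dual-regression back-reconstruction;
    template-based resting-state network identification; conditional Granger
    causality between network time courses with Schwarz-criterion order
    selection and surrogate-based normalization; voxelwise and edge-level
    group statistics with false-discovery-rate control; behavioral
    correlation screening; and leave-one-out support-vector-regression
    prediction of behavioral scores from connectivity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, e1071, jsonlite, yaml, RNifti
Suggests: testthat (>= 3.0.0), kernlab, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'rsnflow-package.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'methods-accessors.R'
    'synthetic.R'
    'groupICA.R'
    'identify.R'
    'cgca.R'
    'predict.R'
    'nifti-io.R'
    'pipeline.R'
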