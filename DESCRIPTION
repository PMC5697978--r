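Package: cognet
Title: Resting-State Cognitive Network Connectivity Deficit Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pipeline for detecting abnormal functional connectivity links in
    predefined cognitive networks from resting-state fMRI. Cleans 4D BOLD data
    by physiological-noise regression and zero-phase low-pass filtering,
    extracts region-averaged signals from an integer-labelled parcellation,
    builds per-subject cross-correlation matrices over five cognitive networks
    (default mode, attention, verbal memory, memory, visuospatial working
    memory), flags links falling outside a control-cohort mean +/- 2 SD
    normative band, and aggregates per-patient deficit counts with one-sample
    t-tests and inter-network correlations. Also provides normalized brain
    volumetry with a thalamus asymmetry index, a Crawford-Howell single-case
    voxelwise comparison of skeletonized fractional-anisotropy maps, and a
    seeded synthetic-data generator producing every input the pipeline
    consumes with a planted covariance, asymmetry and lesion structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    RNifti,
    signal
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'networks.R'
    'simulate.R'
    'preprocess.R'
    'connectivity.R'
    'normative.R'
    'morphometry.R'
    'facompare.R'
    'io.R'
    'pipeline.R'
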