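Package: abstage
Title: Biomarker Staging and Regional Rate Analysis of Early Amyloid-Beta Accumulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for locating the earliest stages of cerebral amyloid-beta
    accumulation from paired cerebrospinal-fluid (CSF) and amyloid-PET
    biomarkers. Provides two-component Gaussian mixture modelling of biomarker
    distributions to derive abnormality cut-offs, CSF/PET stage assignment
    (including a "CSF-low" near-threshold band), longitudinal regional SUVR
    accumulation-rate contrasts with covariate adjustment and
    Benjamini-Hochberg false-discovery-rate control, voxelwise
    covariate-adjusted t-maps with cluster-extent thresholding, Jaccard
    quantification of cluster overlap with resting-state network atlases, and
    a permutation-based network-component statistic linking whole-brain
    functional connectivity to CSF amyloid-beta 42. A synthetic cohort
    generator emulating the statistical structure of such studies makes every
    stage testable without access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    RNifti,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'accumulation.R'
    'component.R'
    'io.R'
    'massUnivariate.R'
    'overlap.R'
    'staging.R'
    'synthetic.R'
    'pipeline.R'
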