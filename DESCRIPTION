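Package: fcdcoupling
Title: Functional Connectivity Density Mapping and Molecular Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise functional connectivity density (FCD) mapping from
    resting-state BOLD volumes and its association with molecular density
    maps such as receptor PET standardized uptake value ratio (SUVR) images.
    Implements local FCD by threshold-constrained cluster growing, global
    FCD by exhaustive supra-threshold edge counting, long-range FCD as their
    difference, white-matter reference SUVR normalization with gray-matter
    and SUVR > 1 restriction, Gaussian volumetric smoothing, ROI and network
    aggregation against a labeled parcellation, Spearman/Fisher-z group
    inference with two-step Bonferroni plus spin-based spatial permutation
    correction on icosphere meshes, and a seeded synthetic-study generator
    with planted hub structure for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'fcdcoupling-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'grid.R'
    'io.R'
    'smoothing.R'
    'masks.R'
    'fcd.R'
    'sphere.R'
    'spin.R'
    'stats.R'
    'synthetic.R'
    'pipeline.R'
LinkingTo:
    Rcpp
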