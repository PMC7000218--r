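Package: ZnFate
Title: Single-Cell Analysis of Zinc-Deficiency-Induced Quiescence and
    Cell-Cycle Stalling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying proliferation-quiescence decisions in
    single-cell time-lapse microscopy. Implements nuclear segmentation and
    tracking of H2B movies, mitosis detection from chromatin condensation
    signatures, perinuclear-ring quantification of CDK2 translocation
    reporters, post-mitosis fate classification (CDK2inc / CDK2emerge /
    CDK2low), S-phase stall detection, mitosis-window binning around a
    perturbation, Hill-model calibration of FRET zinc sensors, nuclear foci
    scoring (53BP1/RPA2) stratified by phospho-Rb state, and EdU/DNA-content
    cell-cycle phase gating. A synthetic-data generator with exact ground
    truth emulates the statistical structure of the underlying experiments so
    every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    EBImage,
    mclust,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: CellBiology, SingleCell, TimeCourse, Visualization, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'calibration.R'
    'segmentation.R'
    'fixed-cell.R'
    'reporters.R'
    'fate.R'
    'synthetic-traces.R'
    'io.R'
    'cli.R'
    'synthetic-movie.R'
    'synthetic-fixed.R'
    'tracking.R'
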