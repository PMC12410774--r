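Package: LymphoDyn4D
Title: Motility Features, Temporal Cell Graphs and Behavior Classification
    for 4D Lymphocyte Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for time-lapse 3D (4D) lymphocyte tracking
    data exported from spot-tracking software. Reads per-frame centroid
    track tables, filters tracks by minimum duration, computes per-track
    motility features (displacement length, track length, mean speed,
    straightness, mean intensity), characterizes motion via time-averaged
    mean squared displacement and the anomalous-diffusion exponent, builds
    per-frame unit-disc proximity graphs (contact radius 7 micrometers) to
    derive cell-cell contact events and per-track contact statistics,
    classifies tracks into track types (low motion, moving-and-turning,
    long-distance) and action types (passive, interactive, active) with a
    random-forest classifier evaluated by repeated stratified
    cross-validation, and compares type distributions and motility between
    cohorts (e.g. reactive versus neoplastic lymphoid tissue). A seeded
    synthetic 4D track simulator with ground-truth labels supports
    end-to-end testing without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'trackio.R'
    'motility.R'
    'msd.R'
    'graphs.R'
    'contacts.R'
    'classify.R'
    'simulate.R'
    'cohort.R'
    'pipeline.R'
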