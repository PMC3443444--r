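Package: octgraft
Title: Segmentation and Area Measurement of Endothelial Keratoplasty Grafts
    in Anterior-Segment OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated and semi-automated segmentation of a DSAEK
    (Descemet stripping automated endothelial keratoplasty) graft from
    calibrated anterior-segment OCT B-scan images. The pipeline extracts
    the graft boundary with a Canny edge detector, locates the four graft
    corner points from local curvature of the sampled boundary, recovers
    the low-contrast host-graft interface, and fits corner-anchored
    smoothing splines to obtain a closed graft segmentation. From the
    segmentation it computes the cross-sectional graft area in square
    microns, the full thickness profile, and a trephine-based volume
    estimate. Observer-agreement statistics (Bland-Altman limits of
    agreement, two-way intraclass correlation with confidence intervals,
    Pearson correlation, paired t-tests) are provided for validating
    repeated measurement series. A synthetic phantom generator with
    analytically known graft geometry supplies ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    png,
    tiff,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'calibration.R'
    'agreement.R'
    'boundary_extraction.R'
    'graft_segmentation.R'
    'graft_metrics.R'
    'config.R'
    'batch.R'
    'oct_io.R'
    'phantom.R'
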