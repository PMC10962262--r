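Package: zebrafishOMR
Title: Behavioral Profiling of Adult Zebrafish in Multi-Tank Optomotor Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-lapse imaging of adult zebrafish in an
    eight-tank arena with moving-line (optomotor) visual stimulation. Detects
    one fish per tank from the red channel of each frame by thresholded
    particle analysis (centroid, bounding box, moment-based best-fit ellipse),
    converts the detection stream into per-frame behavioral metrics (speed,
    movement, end-zone and right-half occupancy, body orientation,
    right-flank-to-center circling), aggregates them over the 18 ten-minute
    periods of the 3-h trial into a 24-measure behavioral profile per fish,
    and provides hexagonal occupancy maps plus the repeated-measures
    statistical layer (Friedman rank sum, Wilcoxon signed rank, one-way
    repeated-measures ANOVA, Bonferroni-adjusted pairwise post-hocs). A
    ground-truthed synthetic generator simulates tank trajectories with
    tunable thigmotaxis, optomotor drift, startle and habituation, and renders
    them as frames with red stripe stimuli, so every stage of the pipeline can
    be validated against known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    png,
    tiff,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
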