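Package: vagalfc
Title: Vagal Modulation and Seed-Based Hippocampal Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline linking exercise-induced vagal
    modulation to seed-based resting-state functional connectivity. Provides
    time-domain heart rate variability analysis (RMSSD, mean heart rate,
    adaptive RR artifact filtering, photoplethysmogram pulse detection),
    sliding-window RMSSD tracking with deflection-point/vagal-threshold
    detection during incremental exercise, incremental-exercise-test fitness
    metrics (VO2max from 10-s binned gas exchange, interpolated maximal power,
    lactate-based aerobic threshold), seed-sphere Fisher-z connectivity maps
    from 4D BOLD volumes with detrending, band-pass filtering, confound
    regression and Gaussian smoothing, and group inference: voxelwise
    Group-by-Time interaction maps, permutation-based cluster-level
    family-wise error control, post-hoc t-tests, MANOVA on autonomic scalars
    and correlation of connectivity change with autonomic change. A synthetic
    data module generates every input class with known ground truth so the
    whole chain is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
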