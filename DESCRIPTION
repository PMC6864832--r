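Package: gazerange
Title: Marker-Based Head Pose Estimation and Driver Gaze-Range Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Offline analysis toolkit for wearable eye-tracker recordings of
    car drivers. Estimates head yaw, pitch and roll from a forward-facing
    view camera by template matching against four printed windshield markers
    (with roll-axis coordinate correction, reference-position calibration and
    extrapolation of the off-screen marker, and motion-aware search-window
    planning), fuses the head angles with eye-in-head angles into a gaze
    signal, classifies each gaze sample into one of nine cabin zones, and
    quantifies a driver's gaze range from the 2-D gaze histogram via a
    per-axis peak-relative threshold rule and Gaussian fitting. Includes a
    fully ground-truthed synthetic scene generator so the whole pipeline is
    testable without any recording hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
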