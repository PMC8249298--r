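Package: flagbeat
Title: Three-Dimensional Flagellar Beat and Swimming Path Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of three-dimensional flagellar beat patterns and the
    swimming behavior they generate. Provides gyration-tensor co-moving
    frames and non-planarity measures, a robust sliding-window estimator of
    signed curvature and torsion for noisy space curves (osculating-plane
    fits with a continuity prior and Taubin circle fits), curvature/torsion
    kymographs and their auto- and cross-correlation statistics, two-segment
    non-planarity and torsion-point localization, head-trajectory metrics
    (averaged path, speed, yaw rate, out-of-plane excursion, beat
    frequency), a resistive-force-theory simulator mapping prescribed beat
    patterns to swimming trajectories, a cone-search filament tracker for
    intensity volumes, and a synthetic beat generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    tiff
Config/testthat/edition: 3
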