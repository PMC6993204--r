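Package: needlekin
Title: Kinematic and Force Metrics for Robot-Assisted Surgical Needle Driving
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for surgeon-centered assessment of surgical
    needle driving from 6-DOF tooltip pose and tissue interaction force/torque
    recordings. Provides synthetic trial and cohort generators (arc-shaped
    insertion trajectories, phase-structured force patterns, speed-curvature-
    torsion power-law trajectories, cohorts with injectable learning effects),
    preprocessing to a uniform 100 Hz grid (shape-preserving cubic and
    spherical-linear quaternion interpolation, zero-phase Butterworth
    filtering, filtered derivative chains), force-threshold trial and subtask
    segmentation, a fifteen-metric suite (completion time, exit-point error,
    normalized force, dynamic-time-warping force and trajectory consistency,
    circle and plane deviation, normalized angular path, one-sixth power-law
    fits, root-mean-squared jerk), and nonparametric contrast statistics
    (block medians, Wilcoxon signed-rank, Kruskal-Wallis, bootstrap
    confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    mgcv,
    signal,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
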