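Package: polscope
Title: Metabolism-Boldness (Pace-of-Life Syndrome) Analysis for Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for testing the pace-of-life
    syndrome (POLS) hypothesis in laboratory zebrafish. Simulates novel-tank
    3D swim trajectories and closed-chamber respirometry sessions with known
    latent structure (a tunable metabolism-boldness correlation), extracts
    the standard novel-tank behavioral measures (bottom distance, center
    distance, distance traveled, voxel exploration, immobility, maximum
    velocity) and blank-corrected mass-normalized routine metabolic rate,
    builds a composite boldness index from within-group z-scores, and runs
    the full statistical battery: normality-gated correlations, bootstrap
    intraclass-correlation repeatability, raw-permutation factorial ANOVA
    with eta-squared, and normality-gated two-group tests with Cohen's d.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
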