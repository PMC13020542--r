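Package: noisenight
Title: Simulation and Analysis of Night-Time Road-Traffic-Noise Crossover Studies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for acute night-time road-traffic-noise exposure studies with
    a randomized crossover design. Generates synthetic exposure nights (playback
    schedules, 1 Hz sound-level and heart-rate traces with known ground truth),
    crossover cohorts and targeted-proteomics (NPX) matrices; detects noise and
    heart-rate peaks by a percentile run-length rule with detrending and a
    minimum-separation merge; pairs noise peaks with heart-rate responses; fits
    the crossover linear and logistic mixed models (condition means, pairwise
    differences, odds ratios with Wald intervals); and runs the responder
    stratification proteomics workflow (pairwise changes, t-test retention,
    z-normalised clustering, PCA, score-thresholded interaction networks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    igraph,
    jsonlite,
    optparse,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
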