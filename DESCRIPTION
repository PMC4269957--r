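Package: impactkin
Title: Closed-Head Impact Kinematics, Histomorphometry and Behavioral Injury Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for pneumatic closed-head impact (CHIMERA-style)
    traumatic brain injury experiments in rodents. Converts two-marker
    high-speed-video head trajectories into filtered linear and angular
    kinematics, peak summaries, repeatability statistics and head-equivalent
    impact energy; scales murine kinematics to human-equivalent values under
    equal-stress/equal-velocity scaling; fits and inverts the impactor's air
    pressure to piston velocity/energy calibration; quantifies white-matter
    histomorphometry (box-counting fractal dimension of microglial outlines,
    Iba-1 cell density, percent-positive stain burden); and computes
    behavioral injury indices (neurological severity score, open-field
    thigmotaxis, passive-avoidance latency, fold change and Bonferroni
    helpers). Includes constraint-solving synthetic-data generators for
    impact trajectories, microglial silhouettes, open-field tracks and
    calibration tables so every stage is testable without raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    signal,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    png,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
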