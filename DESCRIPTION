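Package: mazetrack
Title: Video Tracking and Patch-Use Metrics for Small Aquatic Foragers in Multi-Patch Mazes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Measurement chain for space-use behaviour of single small aquatic
    macroinvertebrates foraging in a backlit multi-patch maze: background-subtraction
    tracking of a dark silhouette in grayscale image stacks, trajectory linking and
    gap filling, maze geometry with circular patches and three-subzone channels,
    a directional zone-transition state machine, visit and giving-up-time accounting,
    locomotory statistics with wall exclusion, rank-based one- and two-factor tests
    (Kruskal-Wallis, Scheirer-Ray-Hare), allometric scaling and logistic occupancy
    models, and a correlated-random-walk simulator with ground-truth logs and a
    near-infrared-style video renderer for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
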