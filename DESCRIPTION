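Package: chemotaxRL
Title: Reinforcement Learning of Chemotactic Navigation for
    Frenet-Serret Microswimmers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a beat-cycle-averaged sperm cell whose swimming
    path follows Frenet-Serret dynamics and which learns chemotaxis
    toward a point chemoattractant source by tabular Q-learning acting
    on path curvature (and torsion in three dimensions).  Includes
    coarse-grained receptor-binding signal noise and flagellar curvature
    noise, a stimulus-response adaptation model for benchmarking, and
    multi-trial experiment drivers that compute success rates,
    time-to-target statistics and learning-parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
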