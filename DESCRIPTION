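Package: myxoglide
Title: Cell-Based Simulation of Myxococcus xanthus Gliding and Early
    Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An off-lattice, agent-based simulator of Myxococcus xanthus
    gliding motility and early aggregation-center formation. Cells are
    flexible node chains gliding on a periodic two-dimensional surface
    under five experimentally motivated behavioral rules: basic motility
    with collision alignment, periodic polarity reversal, density-dependent
    reversal modulation (quorum sensing), extracellular polysaccharide
    (EPS) slime deposition with acute-angle trail following, and
    spontaneous active turning. Includes wild-type and mutant experiment
    presets, density-preserving desk-scale reductions, and analysis tools
    that detect aggregation centers, classify their shapes, and recover
    behavioral statistics from simulated event logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
SystemRequirements: C++17
Config/testthat/edition: 3
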