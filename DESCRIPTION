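Package: ommaquant
Title: Quantitative Analysis of Compound-Eye Surface Order, Ommatidial
    Orientation and Phototaxis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatial-order, circular-statistics, morphometric and behavioral
    analyses for Drosophila compound-eye phenotyping. Estimates the
    density-normalized radial distribution function (pair correlation) of
    corneal-nipple point patterns, builds density-matched hard-core null
    ensembles by random sequential adsorption, and fits a four-parameter
    hard-core disk model (minimum spacing, peak amplitude, decay length,
    oscillation period) to empirical curves. Summarizes ommatidial
    orientation angles with circular means and mean resultant lengths and
    tests group differences with Watson's U-squared and resultant-length
    statistics under a stratified (within-eye) permutation null with the
    (k+1)/(n+1) small-sample correction. Includes polygon shape descriptors
    with fiduciary-bead length calibration, bristle-class tallies,
    countercurrent phototaxis scoring, and a synthetic-data module that
    generates every input type the analyses consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
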