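Package: ffosheets
Title: Simulation and Spatial Statistics for Membrane Protein Sheet
    Lattices in 3D Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests whether membrane-bound protein assemblies observed by
    single-molecule localization microscopy (SMLM/PALM) are organised as
    two-dimensional sheets of laterally packed filamentous oligomers.
    Provides a geometric simulator of labelled dimers, filaments and sheet
    lattices with detection thinning and localization noise; a
    shell-count neighbour statistic (a modified Ripley's K) with a
    Monte-Carlo complete-spatial-randomness null and fold-increase curves
    with standard-deviation bands; localization-table input/output with
    per-frame merging, drift correction and z-slicing; anisotropic
    mixed-Gaussian density rendering; and Fourier periodicity analysis of
    lattice striation images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ggplot2,
    stats,
    utils,
    tiff,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
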