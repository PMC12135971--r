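Package: harddisk2d
Title: Structure Factors of Randomly Packed Hard Disks in Two Dimensions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte Carlo simulation of the two-dimensional hard-disk fluid
    (equivalently, densely packed parallel cylinders) and computation of its
    structure factor as a function of area fraction. Provides Metropolis
    sampling with a tile-based collision check, pair-distribution estimation
    normalized by the distance density of random points in a circle, the
    zero-order Hankel transform to S(Q) with truncation and tapering, a
    smoothed (area fraction, Q) spline tabulation, the Rosenfeld analytic
    hard-disk structure factor, and the cylinder form-factor product model
    used to interpret small-angle scattering from packed fibrillar systems
    such as cellulose microfibrils and collagen.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    splines,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
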