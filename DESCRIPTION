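Package: climExposure
Title: Climate-Change Velocity and Minimum Cumulative Exposure from
    Least-Cost Climate Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Distance-based climate-change velocity with explicit climatic
    resistance to movement. For every pixel of a paired current/future mean
    annual temperature raster the package finds the least-exposure trajectory
    to a future climate analogue over a composite cost surface built from
    temporally interpolated temperature fields, and reports Euclidean and
    minimum-exposure distances (ED, MED), the velocities derived from them,
    the minimum cumulative exposure (MCE, in degrees Celsius) accumulated
    along each trajectory, forward and reverse trajectories, a bivariate
    velocity/MCE exposure classification with island exclusion, synthetic
    benchmark landscapes with known ground truth, and a sensitivity-analysis
    sweep over resolution, analogue bin width and dissimilarity penalty.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
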