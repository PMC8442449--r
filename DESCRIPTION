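Package: magnav
Title: Simulation of Geomagnetic Navigation Strategies During Bird Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A simulation experiment for testing geomagnetic map-and-compass
    navigation strategies during long-distance bird migration. Provides biased
    correlated random walks and correlated random bridges over dynamic
    geomagnetic rasters (intensity F, inclination I, horizontal component H),
    five strategy-specific probability surfaces (no bias, taxis, constant
    heading, bi-gradient map, and their combination), three trajectory
    similarity measures (mean distance, dynamic time warping, dynamic
    interaction index), mixed-model strategy comparison with top-decile
    counting, GPS track preprocessing, and a synthetic generator for
    geomagnetic field stacks and migration tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
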