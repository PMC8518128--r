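Package: spatlink
Title: Unified Translation Between Single-Species Spatial Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links five widely used single-species spatial metrics through
    the second-order intensity function of a point pattern: the
    occupancy-area curve, Taylor's Law, the neighborhood density (O-ring)
    function, a two-plot variant of Taylor's Law (covariance in abundance
    versus inter-plot distance) and two-plot turnover.  Any one metric's
    parametric form can be translated into the other four under the
    assumptions of an orderly, homogeneous, isotropic pattern and a
    negative binomial quadrat-count distribution.  Provides complete
    spatial randomness and Thomas cluster process simulators, direct
    estimators of all five metrics from stem maps, closed-form and
    numerical theory for Gaussian and power-law second-order intensities,
    a three-component bivariate negative binomial layer for joint
    occupancy, per-metric parameter fitting (least squares and minimum
    contrast on the pair correlation function) and scripted simulation
    and multi-species study drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
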