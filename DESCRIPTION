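Package: fieldscan
Title: Multitask Gaussian Process Imputation and MCUSUM Spatial Scan
    Charts for Sensor Field Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@fieldscan.org",
           role = c("aut", "cre"))
Description: Tools for monitoring spatially correlated dynamic fields
    observed through sensor networks with substantial missing data. Missing
    sensor values of a target process are imputed at every time slice by a
    multitask Gaussian process model that pools information across related
    processes, fitted by an expectation-maximization algorithm under a
    normal-inverse-Wishart hyper-prior. Emerging out-of-control spatial
    clusters are then detected with a likelihood-ratio based multivariate
    CUSUM control chart that scans circular clusters of every center and
    radius, for known or unknown shift directions. Control limits are
    calibrated to a target in-control average run length by Monte Carlo
    simulation, and out-of-control run lengths are estimated for simulated
    outbreak scenarios. Includes a synthetic spatiotemporal data generator,
    plain-text panel and configuration file formats, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
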