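Package: vegresilience
Title: Vegetation Resilience Estimation from Deseasonalized Index Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates vegetation resilience from bi-weekly vegetation index
    time series in three complementary ways: the empirical recovery rate
    fitted to exponential relaxation after abrupt negative perturbations,
    and two theory-based restoring rates derived from the lag-one
    autocorrelation and the variance of the seasonal-trend decomposition
    (STL) residual, under a linearized Ornstein-Uhlenbeck model. Computes
    water-availability covariates (aridity, Walsh-Lawler seasonality index,
    normalized inter-annual precipitation variability) and quantifies
    resilience-water relationships per land-cover class via binned medians
    with Kendall-tau statistics and Monte-Carlo surrogate significance.
    Includes a synthetic-landscape generator with known ground truth for
    validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    zoo,
    minpack.lm,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
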