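Package: clusterbias
Title: Consequences of Ignoring Clustering in Linear Regression
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Monte-Carlo machinery for studying what happens when ordinary
    least squares regression is applied to clustered data that were generated
    under a random-intercept model. Provides a clustered-data generator with
    intraclass-correlation (ICC) target-range acceptance-rejection, a fast
    profiled maximum-likelihood fitter for the balanced random-intercept
    model alongside the cluster-unadjusted OLS fit, and evaluation tools for
    bias, relative precision (SE ratios), 95% confidence-interval coverage
    and Type I error, stratified by ICC level and by the between-cluster
    dispersion of the explanatory variable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    ggplot2
Config/testthat/edition: 3
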