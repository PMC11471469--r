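Package: duslindley
Title: The DUS Lindley Lifetime Distribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Density, distribution, quantile and random generation for the
    DUS Lindley lifetime distribution, obtained by applying the DUS
    transformation G = (exp(F) - 1)/(e - 1) to the one-parameter Lindley
    baseline (an exponential baseline is also provided). Includes analytic
    summaries (moments, conditional moments, generating functions, mean
    residual and past life, order statistics, Renyi and Tsallis entropies,
    Lorenz and Bonferroni curves) with independent series cross-checks,
    five estimators of the shape parameter (maximum likelihood, least
    squares, weighted least squares, Cramer-von Mises and Anderson-Darling),
    a likelihood-ratio test of the Lindley baseline against its DUS
    transform, series/parallel/series-parallel system reliability,
    a Monte-Carlo bias/variance/MSE study of the maximum likelihood
    estimator, and information-criterion model comparison on positive
    lifetime samples.
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
    generics,
    ggplot2,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
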