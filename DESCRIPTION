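Package: pgsabs
Title: Translating Polygenic Scores onto the Absolute Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts standardized polygenic scores (polygenic Z-scores) from
    the relative to the absolute scale using summary statistics only. For
    binary phenotypes the population score distribution is modelled as a
    two-component normal mixture parameterized by the phenotype prevalence and
    the predictive utility of the score (AUC or an equivalent metric), and the
    probability of being a case is computed within any score quantile or for
    any individual Z-score. For normally distributed phenotypes the score and
    trait are modelled as bivariate normal, yielding the trait mean, standard
    deviation and prediction interval within any score quantile. Includes
    conversions among common polygenic score effect-size metrics (AUC, Cohen's
    d, point-biserial correlation, odds ratio per standard deviation, observed-
    and liability-scale R-squared), a simulation module that generates
    synthetic cohorts with the assumed statistical structure for validation,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
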