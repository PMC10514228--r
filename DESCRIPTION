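Package: twinpath
Title: Liability-Threshold Twin Models for Binary Phenotypes by Two-Stage
    Weighted Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate biometric modelling of binary (lifetime) phenotypes
    measured on monozygotic and dizygotic twin pairs. Stage one estimates
    sex-specific liability thresholds and within- and cross-twin tetrachoric
    correlation matrices per zygosity-sex group, with their asymptotic
    covariance; stage two fits univariate ACE, bivariate Cholesky,
    independent pathway, and common pathway models to those moments by
    (diagonally) weighted least squares. Includes a mean-adjusted fit
    statistic with RMSEA/TLI/CFI indices, Wald tests for nested model
    comparison and quantitative sex differences, sandwich covariances,
    bias-corrected accelerated bootstrap confidence intervals, a model
    ladder for factor-count selection, and a seeded synthetic twin-data
    generator with a preset emulating a large volunteer twin-registry study
    of drug (mis)use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
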