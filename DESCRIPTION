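Package: pairedlcs
Title: The Paired t-Test as a Latent Change Score Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the classical paired t-test and its structural-equation
    reformulation as two-wave latent change score (LCS) models by maximum
    likelihood on mean-and-covariance structures. Provides the correlated
    level-change specification (which reproduces the paired t-test exactly),
    the self-feedback specification in which baseline level predicts change,
    the nested chi-square difference test of the no-self-feedback constraint,
    a sensitivity sweep over the assumed test-retest correlation for analyses
    from published summary statistics only, and a seeded bivariate-normal
    simulation harness for equivalence, type-I error and parameter-recovery
    studies. Results are returned as tibbles with broom-style tidy() and
    glance() methods and ggplot2 autoplot() methods.
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
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    readr,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
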