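Package: trajmix
Title: Growth Mixture Models for Clustering Longitudinal Prevalence Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits finite mixtures of linear latent-growth-curve models
    (growth mixture models) to longitudinal panels of prevalence values,
    such as country-level under-five underweight prevalence, by multi-start
    EM on the class-marginal multivariate-normal likelihood. Provides class
    enumeration via information criteria (AIC, BIC, sample-size-adjusted
    BIC), relative entropy, and a parametric bootstrap likelihood-ratio
    test; parametric-bootstrap and observed-information standard errors;
    modal posterior classification; a synthetic-panel generator with a
    built-in three-class reference scenario; and a config-driven reporting
    pipeline that exports descriptive statistics, fit indices, per-class
    trajectory estimates, and membership tables. Broom-style tidy(),
    glance() and augment() methods plus ggplot2 autoplot() methods are
    supplied for fitted objects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
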