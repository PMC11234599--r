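Package: twinace
Title: Twin Variance-Component Models for Epigenetic Age Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classical twin modelling of quantitative phenotypes such as
    epigenetic age acceleration: univariate ACE/ADE variance decomposition
    with saturated-model references, likelihood-ratio and AIC model
    selection, and profile-likelihood confidence intervals; longitudinal
    bivariate Cholesky models for two measurement waves with derived
    genetic and environmental cross-time correlations, cross-twin
    cross-trait correlations, and decomposition of phenotypic stability;
    age-acceleration residualization and standardization utilities; and a
    synthetic twin-pair generator that draws from the exact model-implied
    moments for monozygotic and dizygotic pairs. All models are fitted by
    full-information maximum likelihood on the multivariate-normal pair
    likelihood.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rlang,
    optparse
Config/testthat/edition: 3
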