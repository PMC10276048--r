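Package: severomix
Title: Mixed Logit Injury-Severity Models with Heterogeneity in Means and Variances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling three-level crash injury severity (minor, severe,
    fatal) with mixed (random-parameters) logit models whose random coefficients
    carry heterogeneity in both their means and their variances.  Estimation is by
    simulated maximum likelihood over Halton draws, with analytic gradients.
    Includes average marginal effects for binary covariates, likelihood-ratio
    transferability and temporal-instability tests between subgroup models,
    out-of-sample prediction simulation, a synthetic crash-data generator with
    known truth for recovery experiments, descriptive statistics and a Pearson
    multicollinearity screen, YAML model-specification configs, and
    publication-style table rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
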