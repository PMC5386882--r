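Package: gestwin
Title: Time-to-Event Simulation of Gestational Age with Time-Variant
    Genetic Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates gestational age as a survival phenotype in relative
    pairs under a Gompertz baseline hazard multiplied by genetic effects
    that are either constant across gestation or confined to Gaussian
    windows of sensitivity. Provides sibling genotype simulation under
    Hardy-Weinberg equilibrium, analytic and iterative survival-time
    engines, conditional-quantile summaries of paired phenotypes with a
    square-root-weighted sum-of-squares cost, meta-model random-search
    fitting of nested model families, and empirical power and type-I-error
    analysis comparing linear and Cox regression for locus detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    flexsurv,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
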