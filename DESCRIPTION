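Package: aridishift
Title: Aridity-Driven Shifts in Biodiversity-Multifunctionality Relationships
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how the relationships between plant or soil
    microbial diversity and soil multifunctionality change along aridity
    gradients in drylands. Implements averaging and multiple-threshold
    multifunctionality indices, change-point ("aridity threshold") detection
    by step/segmented/stegmented regressions with AIC selection and bootstrap
    validation, linear mixed-effects models with sequential (type-I) ANOVA,
    variance inflation screening and marginal/conditional R-squared, and a
    moving-window bootstrap of standardized coefficients along the gradient.
    A seeded synthetic-data generator emulates a dryland survey with a
    planted change point so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    lmerTest,
    mgcv,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
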