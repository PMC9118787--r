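Package: templag
Title: Temporal Cross-Lagged Analysis of Adiposity and the Gut Metagenome
Version: 1.0.0
Authors@R:
    person("templag", "developers", email = "templag@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal analyses linking adiposity, gut
    metagenome features, and insulin resistance in paired-visit cohorts:
    abundance-table import with prevalence filtering and zero-replaced log
    transforms, alpha/beta diversity, confounder residualization feeding a
    closed-form cross-lagged panel model with SRMR/CFI fit indices and
    Benjamini-Hochberg screening, weight-change-pattern and mixed-effect
    microbe-phenotype association models, quasi-Bayesian causal mediation
    (ACME/ADE/proportion mediated), DerSimonian-Laird random-effects
    meta-analytic replication, and a synthetic cohort generator with known
    cross-lag and mediation truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
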