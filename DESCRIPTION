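Package: blisstrial
Title: Bliss Independence and Randomised-Block Analysis of Biocontrol Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical pipeline for randomised-block biocontrol field
    trials against the large pine weevil (Hylobius abietis). Implements
    cross-tabulation chi-square analysis with standardized residuals and
    Cramer's V, the Bliss independence synergy test for combined
    fungus-plus-nematode treatments, negative binomial emergence models with
    likelihood-ratio tests, estimated marginal means and Dunnett-style
    many-to-one contrasts, and non-target community analysis (distance
    matrices, principal co-ordinates analysis, the multi-response
    permutation procedure and one-way ANOVA). A synthetic-data generator
    reproduces the statistical structure of destructive-sampling records,
    per-stump emergence counts and trap-by-taxon community matrices so the
    whole pipeline is testable without raw field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    glmmTMB,
    vegan,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    withr
Config/testthat/edition: 3
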