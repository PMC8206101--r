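Package: regretwheel
Title: Two-Stage Analysis of Regret-Guided Risky Choice in Social Context
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the Wheel-of-Fortune two-lottery choice paradigm with
    full factual and counterfactual feedback: gamble statistics (expected
    value, outcome standard deviation, anticipated regret), a generative
    simulator of the 2x2 beneficiary-by-audience design, per-condition
    mixed-effects logistic and linear models of choices and emotional
    ratings, two-stage inference via repeated-measures ANOVA on per-subject
    coefficients with partial eta-squared confidence intervals, and
    simulation harnesses for type-I error and power of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
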