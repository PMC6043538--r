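Package: membias
Title: Memory Bias on Value-Based Decisions from Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the remember-and-decide paradigm, in which
    choice options must be retrieved from memory before a value-based decision
    can be made. Provides per-participant statistics (the memory-bias logistic
    intercept, its forgotten-value-corrected variant, linear and quadratic
    value-dependency of cued-recall performance and of self-estimated memory),
    summed-deviance likelihood-ratio model comparisons, per-participant
    recursive path/mediation analysis, and cohort-level inference (one-sample
    t-tests with Cohen's d, Pearson correlations, normality checks, and a
    Fisher-z power analysis for correlation tests). A generative simulator of
    the full task -- constrained trial-set construction, encoding, recall,
    paired decisions, and memory estimation -- supports parameter-recovery and
    calibration studies without any experimental data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
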