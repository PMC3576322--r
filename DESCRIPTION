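Package: ramtc
Title: Bayesian Mixed Treatment Comparisons of Anti-TNF Agents in
    Rheumatoid Arthritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian network meta-analysis (mixed treatment
    comparison) of placebo-controlled trials of the five anti-TNF agents
    licensed for rheumatoid arthritis, on both continuous and binary
    efficacy measures.  Implements arm-level data preprocessing with the
    standard missing-summary rules (median substitution, IQR-based and
    maximum-SD imputation), reconstruction of a continuous ACR response
    from nested ACR 20/50/70 responder counts, dichotomization of the
    continuous HAQ improvement into HAQ 20/50 responders, random-effects
    MTC models for multi-arm trials with an additive methotrexate term
    and a baseline-HAQ multiplier, Gibbs-sampling inference through JAGS,
    pairwise efficacy summaries with equal-tailed credible intervals and
    forest plots, and a synthetic trial-network generator for parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    coda,
    graphics,
    grDevices,
    rjags,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
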