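Package: discountr
Title: Delay Discounting Task Design, Choice Modeling and Group Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for intertemporal-choice (delay discounting) studies:
    generation of binary choice tasks between a fixed immediate reward and
    uniformly spaced delayed rewards, an adaptive bisection pretest for a
    provisional discount rate, hyperbolic subjective-value and softmax choice
    modeling, per-subject maximum-likelihood estimation of the discount rate
    and decision noise, a hierarchical Bayesian model with truncated-normal
    group hyper-distributions sampled by Metropolis-within-Gibbs, model-free
    indifference-point and area-under-the-curve (AUC) analysis, and the group
    comparison battery (paired and independent t-tests, Mann-Whitney U,
    chi-square, test-retest correlations). Includes a synthetic-cohort
    generator with known ground truth for end-to-end validation of the whole
    pipeline in a two-group, two-session design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    coda,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rjags,
    optparse
Config/testthat/edition: 3
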