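Package: symptomLCA
Title: Longitudinal Latent Class Models for Childhood Allergic Symptom
    Trajectories
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Author: Package Maintainer
Maintainer: Package Maintainer <maintainer@example.org>
Description: Fits competing Bayesian latent-class models to longitudinal
    panels of binary allergic symptom indicators (eczema, wheeze, rhinitis)
    observed at discrete childhood ages in birth cohorts: class-conditional
    independent Markov chains, a cross-symptom "atopic march" Markov model,
    and an unconstrained latent disease profile mixture. Provides MAP
    expectation-maximisation inference with exact marginalisation of missing
    observations, hold-out and BIC model evidence, class-number sweeps with a
    stability-based convergence rule, Dirichlet-pseudocount prior sensitivity
    analysis, class trajectory profiling, and contingency-table association
    statistics (Woolf odds-ratio confidence intervals, Pearson chi-square
    tests). Includes a synthetic-cohort generator emulating the two-cohort
    data structure (structural and random missingness, derived asthma and
    sensitisation variables, inclusion filters) so the full pipeline is
    testable without access to individual-level cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
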