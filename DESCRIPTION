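Package: survbiasim
Title: Monte-Carlo Simulation of Survival Bias and Treatment
    Effect-Modification in Genetic Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates cross-sectional case-control studies of a binary
    genetic risk factor to quantify how the exclusion of fatal cases
    (survival / incidence-prevalence bias) and genotype-specific drug
    benefit (effect-measure modification by statin use) attenuate the
    estimated odds ratio relative to the prospective risk ratio. Cohorts
    are synthesized from a banded age-by-sex population distribution and
    a cumulative cardiovascular-incidence surface, events are drawn by
    Bernoulli sampling against per-individual risk, fatal cases are
    removed under genotype-specific case-fatality rates constrained to a
    fixed overall rate, and the carrier odds ratio is estimated by
    logistic regression adjusted for age and sex. A closed-form
    expected-count oracle provides deterministic predictions for every
    simulated condition, used for calibration and for equivalence
    testing of the stochastic engine. Includes grid runners for the
    canonical fatality-differential and statin-use experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2,
    optparse,
    yaml
Config/testthat/edition: 3
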