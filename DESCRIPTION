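Package: discountr
Title: Delay Discounting of Rewards and Losses: Task Design, Model Fitting, and Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intertemporal-choice studies of delay discounting.
    Generates the 96-trial reward/loss choice design by inverting a hyperboloid
    value model at target choice probabilities, fits the modified hyperboloid
    discounting model (kappa, s, beta) to trial-level choices by bounded
    multi-start maximum likelihood, scores the accompanying questionnaires
    (AUDIT, DDQ, BIS-15) and socioeconomic variables, simulates full synthetic
    cohorts with a Gaussian copula matched to published correlation targets,
    and runs the confirmatory (H1-H5) and exploratory regression analyses,
    including delta-R-squared and semipartial confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    tibble
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
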