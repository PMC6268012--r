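Package: lcchoice
Title: Latent-Class Discrete Choice Models with Utility- and Regret-Based Segments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of latent-class multinomial logit models in which latent
    segments may follow different decision rules: random utility maximization
    (RUM) or random regret minimization (RRM), with optional within-segment
    random (mixed) coefficients estimated by maximum simulated likelihood over
    randomized Halton draws. Includes logit membership models on respondent
    covariates, BIC/AIC model comparison and a greedy search over segment
    compositions, posterior segment assignment and population shares,
    time-based trade-off (willingness-to-travel) computation for both decision
    rules, and a stated-preference panel simulator for partitioned
    route-choice experiment designs.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
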