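Package: qreug
Title: Quantal Response Equilibrium Analysis of Ultimatum Game Experiments
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Structural estimation of social preferences from discrete
    ultimatum game data. Solves the agent quantal response (logit)
    equilibrium of the 11-offer ultimatum game under symmetric quadratic
    inequality-averse utility, fits the fairness coefficient b and the
    logit rationality coefficient lambda by maximum likelihood per
    population group or under shared-parameter restrictions, and provides
    bootstrap standard errors, likelihood-ratio tests of nested models,
    descriptive summaries, a binned-count reconstruction utility with the
    Zimbabwe resettlement field-experiment tables embedded as fixtures,
    and an equilibrium-based synthetic data generator with a
    parameter-recovery harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
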