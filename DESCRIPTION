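Package: qmulti
Title: Q-Methodology Analysis of Forced-Distribution Preference Sorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Q-sort preference data collected over
    factorial multi-sensory stimulus designs. Participants rank a full
    factorial set of stimuli into a forced quasi-normal grid; the package
    models overall and per-cluster level preferences with an ordered-probit
    cumulative-link model and Wald block tests, quantifies how strongly each
    design variable drives a sort via normalized grid-spread dominance
    weights tested by analysis of variance, and identifies clusters of
    like-minded participants with by-person (Q) factor analysis: principal
    component extraction, varimax rotation, automatic exemplar flagging and
    idealized factor arrays. A latent-utility synthetic-sort generator with
    planted cluster structure makes every stage testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
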