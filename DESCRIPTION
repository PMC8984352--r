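Package: proxbond
Title: Analysis of Forced-Proximity Experiments on Dyadic Allogrooming Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse experiments that force randomly selected groups
    of previously unfamiliar animals into close proximity and ask whether the
    manipulation creates enduring cooperative relationships. The package
    computes exposure-weighted dyadic allogrooming log rates per experimental
    phase, classifies dyads by familiarity and treatment, and provides the
    resampling inference the design calls for: percentile-bootstrap confidence
    intervals on mean rate changes, a constrained permutation test that
    re-randomizes the site-complete triad assignment, rank-based follow-up
    models with within-cage permutation nulls, and Spearman correlations
    between phase rates. A synthetic colony generator with a tunable
    treatment effect makes the whole pipeline runnable and testable without
    any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
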