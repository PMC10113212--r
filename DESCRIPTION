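Package: lineupmpt
Title: Lineup Fairness from Eyewitness Data via a Two-High-Threshold
    Multinomial Processing Tree Model
Version: 1.0.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring the fairness of police lineups. Implements
    the two-high-threshold (2-HT) eyewitness identification model, a
    multinomial processing tree over the six response categories observable
    in culprit-present and culprit-absent lineups, together with joint
    maximum-likelihood estimation across experimental conditions under
    equality restrictions, likelihood-ratio G-squared goodness-of-fit tests,
    nested-model comparisons with Cohen's w effect sizes, and noncentral
    chi-square sensitivity analysis.  Also provides the classical
    mock-witness fairness measures (Tredoux's E effective lineup size,
    proportion of suspect selections, pooled two-proportion z test) and
    their "resultant" counterparts computed from culprit-absent eyewitness
    identifications, a multinomial simulator for eyewitness and
    mock-witness data, bundled observed-frequency fixtures, and a small
    command-line interface for reproducible analyses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
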