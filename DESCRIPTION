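Package: cpmnet
Title: Connectome-Based Predictive Modeling with Site-Aware Cross-Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Connectome-based predictive modeling (CPM) of prospective
    symptom severity from resting-state functional connectivity. Builds
    Fisher r-to-z connectomes from parcellated time series, screens edges
    by (partial) Spearman rank correlation with the outcome, summarises
    selected edges into a per-participant network-strength score, and
    fits a strength-to-outcome linear model under leave-half-sites-out
    cross-validation with permutation-based significance testing.
    Includes external validation of a fixed edge set in an independent
    cohort, canonical-network characterization of the selected edges, and
    a multi-site, family-nested synthetic cohort generator with planted
    edge-outcome signal for end-to-end testing without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    arrow
Config/testthat/edition: 3
RoxygenNote: 7.3.3
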