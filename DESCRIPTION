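Package: clpnet
Title: Cross-Lagged Panel Network Analysis for Two-Wave Symptom Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and evaluation of cross-lagged panel networks (CLPN)
    for two-wave questionnaire panels: validated panel ingestion, descriptive
    and paired-comparison tables, nonparanormal (Gaussian copula)
    transformation, node-wise cross-validated LASSO estimation of the directed
    wave-1 to wave-2 coefficient matrix with covariate adjustment, edge
    thresholding and summaries, in-/out-prediction centrality via nested
    least-squares variance decompositions, nonparametric bootstrap accuracy
    and case-dropping stability (CS coefficients), subgroup sensitivity
    networks, and a latent-Gaussian synthetic panel generator with
    simulation-based power and recovery analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
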