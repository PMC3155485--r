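Package: collabnet
Title: Dyadic Homophily Analysis of Professional Collaboration Networks
    with MR-QAP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds directed, valued inter-professional collaboration
    networks from sociometric roster and nomination data, derives dyadic
    homophily covariates (absolute attribute differences, same-category
    indicators, co-authorship ties, geographic distance), computes network
    descriptives (density, reciprocity, dyad census), and estimates
    homophily effects by multiple regression quadratic assignment
    procedures (MR-QAP) with Dekker double semi-partialing or
    response-permutation inference. Includes a synthetic sociometric study
    generator with planted tie-model effects for calibration and parameter
    recovery experiments, and an end-to-end pipeline producing
    publication-shaped summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
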