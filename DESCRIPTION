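Package: utsassembly
Title: Assembly Processes and City Specificity of Urban Transit System Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the ecological assembly of urban transit
    system (subway and bus) surface microbiomes and their relationship to
    city characteristics. Implements Sloan neutral community model fitting
    with occurrence-frequency partitioning, null-model stochasticity
    quantification (modified stochasticity ratio and modified Raup-Crick
    beta-diversity), expectation-maximization microbial source tracking with
    an unknown source, transfer-learning random forests (structure
    expansion/reduction) for city classification and delta-AUROC
    city-specificity mining, city-characteristic classification from mined
    genera, and community-ecology association statistics (Mantel, PERMANOVA,
    Shannon diversity, principal-coordinate analysis). Includes a synthetic
    community generator with known assembly processes so every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    vegan,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
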