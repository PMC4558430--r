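Package: crvnet
Title: Differential Protein-Protein Interaction Network Markers via
    Carcinogenesis Relevance Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reverse-engineers condition-specific protein-protein
    interaction networks (PPINs) from expression data by regression-model
    identification (maximum-likelihood estimation with AIC model-order
    selection and t-test pruning), scores each protein's differential
    wiring between cancer and noncancer networks with the carcinogenesis
    relevance value (CRV), assesses significance against a
    degree-preserving permutation null, and classifies core versus
    stage-specific network markers. Includes a synthetic-data generator
    emulating the linear association model, tabular/SIF input-output for
    expression tables, sample sheets and PPI edge lists, and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
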