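Package: pertnet
Title: Perturbation-Signature Network Pharmacology for Target-Gene Modulator Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for identifying small-molecule modulators of a target gene
    (by default the urokinase receptor gene PLAUR/uPAR) from Connectivity-Map
    style compound-by-gene perturbation score matrices, and for downstream
    network-pharmacology analysis: construction of transcriptional and
    translational compound-driver-gene bipartite networks with degree, hub and
    core analysis, protein-protein-interaction core induction, per-pathway
    modulator repetition-rate statistics, a target-driver gene pair rule that
    stratifies compounds as anti-cancer or carcinogenic with cancer-hallmark
    annotation, and a cross-validated machine-learning screening platform
    benchmarking seven classifier families. Includes a synthetic data
    generator with planted ground truth so that every stage of the pipeline
    can be validated without external database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph,
    e1071,
    randomForest,
    nnet,
    xgboost,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    pROC
Config/testthat/edition: 3
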