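Package: tritensor
Title: Drug-Gene-Disease Triple Association Prediction by Generalized
    Tensor Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts drug-gene-disease triple associations by completing a
    sparse binary three-way tensor with an ensemble of generalized tensor
    decomposition (a CP decomposition with a learned output layer and
    sigmoid activation) and per-entity multi-layer perceptron towers, with
    entity side information fused from identifier embeddings and
    drug/gene/disease similarity rows.  Includes multi-level ATC-code drug
    similarity, ontology information-content semantic similarity with
    best-match averaging, entity-wise cold-start cross-validation with
    negative sampling, AUC/NDCG ranking metrics, pairwise association
    prediction from learned latent vectors, and synthetic benchmark
    generators (planted low-rank tensors, toy ontologies, toy ATC code
    sets).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
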