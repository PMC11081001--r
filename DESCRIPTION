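Package: fepfa
Title: Fuzzy-Entropy-Controlled Pathfinder Feature Selection for Staged
    Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for high-dimensional image-derived
    feature matrices, built around the Pathfinder swarm algorithm with a
    k-nearest-neighbour cost function and a second-stage fuzzy C-means
    entropy refinement. Includes lossless image augmentation operators,
    morphological and Laplacian-pyramid contrast enhancement, a
    query/key/value self-attention feature head with an untrained
    ResNet-50 forward pass that emits 2,048 features per image, Gaussian
    process Bayesian optimization over a bounded hyperparameter box,
    multiclass classification metrics (macro precision/recall/F1, Cohen's
    kappa, multiclass Matthews correlation), and a seeded synthetic-data
    generator with planted informative features so the whole pipeline is
    testable without any imaging dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    e1071,
    EBImage,
    jsonlite,
    lhs,
    nnet,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
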