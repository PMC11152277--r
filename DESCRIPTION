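Package: fcalink
Title: Bipartite Link Prediction from Concept Lattices with a
    Position-Free Transformer Encoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for link prediction in bipartite networks (for example
    metabolite-reaction networks) built on formal concept analysis.  The
    package enumerates all formal concepts (maximal bi-cliques) of a
    bipartite network, constructs the concept lattice and its neighbor
    (Hasse) relation, and pre-trains a transformer encoder without
    position embeddings on two tasks derived from the lattice: masked
    token prediction over extents and neighboring-concepts prediction.
    The pre-trained encoder is fine-tuned for object-object (shared
    neighbor) and object-attribute (missing edge) link prediction.
    Includes a planted-bi-clique synthetic network generator, balanced
    labeled-sample construction, threshold-sweep F1/AUC/AUPR evaluation,
    and common-neighbors and Katz-index baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
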