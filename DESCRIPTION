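Package: dyntrans
Title: Neural Linear-Chain CRFs with Context-Dependent Transition Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sequence labeling for biomedical named-entity recognition with a
    linear-chain conditional random field whose label-label transition scores
    are produced dynamically by a neural network from sentence context, rather
    than read from a static transition matrix. Two BiLSTM-based networks - a
    unary network scoring labels per token and a pairwise network scoring label
    pairs per adjacent token pair through a low-rank bilinear interaction - are
    trained jointly as two separate CRFs and combined as a product of models
    for Viterbi decoding. Includes CoNLL corpus input/output with IOB2/IOBES
    scheme conversion, entity-level exact-match evaluation, a synthetic-corpus
    generator with context-dependent entity segmentation for fully offline
    experimentation, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
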