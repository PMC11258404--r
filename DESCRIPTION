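Package: ConcernFusion
Title: Disagreement-Routed Fusion of Multiple Text Encoders for Patient
    Portal Message Triage
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies the single primary-concern class of short free-text
    messages (for example patient portal messages labelled A/L/P/U) by fusing
    several sentence encoders. Fine-tuned baseline classifiers are built over
    each encoder; messages on which the baselines disagree are routed to a
    fusion head (average pooling, additive attention, or a 2-D convolutional
    network over the stacked embeddings) trained on disagreement examples
    only, while unanimous messages keep the consensus label. Includes
    majority-vote ensembles with alphabetical tie-breaking, three
    class-rebalancing strategies (inverse-frequency weights, random
    oversampling, focal loss), a repeated stratified k-fold cross-validation
    harness with per-bucket disagreement analysis, a deterministic mock
    encoder, and a synthetic corpus/embedding generator so the whole pipeline
    is testable without private clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    nnet,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
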