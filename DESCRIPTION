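Package: resilmine
Title: Literature-Based Mining of Community Resilience Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Mines phrase-level community-resilience indicators from a
    document corpus and organises them into a hierarchical indicator
    system. Implements contrastive (InfoNCE) text representations with
    seeded augmentation, a four-phase candidate-phrase screening funnel
    with threshold sensitivity analysis, Poincare-ball embedding of
    indicators evaluated by a Hierarchical Fidelity Score against a
    Euclidean baseline, a multi-head self-attention relation matrix under
    a trace-exponential acyclicity constraint, tangent-space k-means
    clustering with three-metric model selection, inter-rater and Likert
    validation statistics, and framework-overlap accounting. Ships a
    seeded synthetic-corpus generator (planted phrases, topic hierarchy,
    simulated rater panels) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    e1071,
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
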