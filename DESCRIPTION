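Package: pathwayAE
Title: Explainable Autoencoder Prediction from Patient-Pathway Event Logs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts a binary pathway-related outcome from coded medical
    event logs and identifies the predictive factors. Event logs are
    enriched with the code hierarchy, transformed into activity-by-time
    occurrence matrices in [0,1], and used to train dense autoencoders
    (plain, denoising or variational) under a "filter" or "inverse"
    objective that treats the two outcome classes asymmetrically. Scores
    derived from the decoded output classify patients; the difference
    between mean decoded positive and negative matrices yields a global
    explanation map whose top-ranked activities are validated with
    relative risks and 95% confidence intervals. A synthetic event-log
    generator with plantable temporal motifs makes the whole pipeline
    testable without claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
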