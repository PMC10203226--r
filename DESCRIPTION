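Package: wmcircuit
Title: Two-Region Intracranial Working-Memory Representation and
    Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for simultaneous two-region intracranial
    local field potential recordings during a Sternberg working-memory
    task. Provides signal conditioning (zero-phase FIR band-pass,
    DFT line-noise removal, polyphase downsampling, common-average
    re-referencing, epoching), Morlet time-frequency decomposition with
    bootstrap baseline z-scoring, sliding-window representational
    dissimilarity and encoding-maintenance similarity maps, phase slope
    index directional connectivity with trial-shuffle permutation nulls,
    working-memory load decoding via train-only PCA and a linear
    support-vector classifier, cluster-based permutation inference on
    time-time maps, and a synthetic two-region LFP generator with known
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
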