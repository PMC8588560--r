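Package: siamscreen
Title: Siamese Multi-Layer Perceptron Similarity Searching for
    Ligand-Based Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based virtual screening with an enhanced Siamese
    multi-layer perceptron similarity model over extended-connectivity
    count fingerprints. Twin weight-shared encoders feed two fixed
    distance layers (Manhattan and exponential Manhattan) whose outputs
    are fused and passed through a trainable head; the trained network
    scores query-candidate molecule pairs for ranked retrieval. Includes
    signal-to-noise-ratio node pruning with sweep evaluation, top-percent
    recall screening against a continuous-Tanimoto baseline, tie-corrected
    Kendall W concordance ranking of similarity methods, and a calibrated
    synthetic library generator emulating the activity-class structure of
    the MDDR, MUV and DUD benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
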