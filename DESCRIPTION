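Package: psnfuse
Title: Patient Similarity Networks from Static and Longitudinal Clinical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds patient similarity networks (PSNs) from heterogeneous
    clinical data and fuses them for outcome classification. Static patient
    profiles (numeric, categorical, and free-text fields) are compared with
    per-feature similarity rules combined as a weighted sum, or embedded as
    numeric vectors and compared under standard geometric distance measures.
    Variable-length longitudinal visit sequences are compressed to fixed-length
    patient embeddings with a self-contained LSTM encoder-decoder trained on
    masked reconstruction error. The static and dynamic similarity matrices are
    merged by a pairwise weighted-average similarity network fusion with
    row-stochastic normalisation, symmetrisation, and K-nearest-neighbour
    sparsification. Fused networks are scored against patient outcomes with
    pairwise confusion counts, patient-level K-nearest-neighbour majority vote,
    and stratified cross-validation. A seeded synthetic cohort generator with
    controllable static and dynamic outcome signal supports end-to-end testing
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
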