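Package: flossr
Title: Online Semantic Segmentation of Time Series via the Matrix Profile
Version: 0.1.0
Authors@R: person("flossr", "maintainers", email = "flossr@example.org",
    role = c("aut", "cre"))
Description: Domain-agnostic semantic segmentation of one- and
    multi-dimensional time series, in batch (FLUSS) and streaming (FLOSS)
    modes. Computes z-normalized nearest-neighbor structure (the Matrix
    Profile), turns it into arc curves normalized by idealized null models
    (parabolic, one-directional, or temporally constrained uniform), extracts
    regime boundaries with an exclusion-zone search, supports alert-threshold
    learning from negative-only training snippets, a boundary scoring metric,
    a heuristic to learn the subsequence length from rescaled snippets, and a
    seed-deterministic synthetic-data generator with a distortion battery for
    testing. Includes a command-line interface for file-based workflows.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
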