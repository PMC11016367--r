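Package: glula
Title: Efficient Linear-Attention Networks for Human Activity Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a family of compact attention-based neural networks
    for classifying human activities from multichannel body-worn sensor
    time series. The architecture combines gated causal convolutions,
    branched convolutions with a depthwise separable merge, and kernelized
    linear self-attention with an elu(x)+1 feature map, read out through a
    learnable class token. Training uses manifold mixup regularization, a
    one-cycle learning-rate policy and an AdaBelief optimizer, all written
    in base R with exact hand-derived gradients. Includes the standard
    preprocessing chain for wearable-sensor data (linear interpolation of
    missing values, z-score normalization, overlapping sliding windows),
    leave-one-subject-out evaluation with weighted and macro F1 metrics,
    and a synthetic-data generator that emulates the statistical structure
    of wearable-sensor benchmarks so the full pipeline is testable without
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
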