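Package: phenodistill
Title: Knowledge Distillation and Attention Transfer for Single-Image
    Crop Phenology Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Distills a multi-temporal image-series phenology classifier
    (a convolutional backbone with a recurrent temporal head, the
    "teacher") into a single-image classifier (the "student") using
    temperature-softened knowledge distillation combined with multi-layer
    activation-based attention transfer. Provides a synthetic ordinal
    growth-stage image generator, manifest/series dataset handling with
    series-level splits and temporally coherent augmentation, a compact
    CPU neural-network stack (convolutions, LSTM, Adam), the full ordinal
    multi-class metric suite (overall accuracy, macro F1, Cohen's kappa,
    ordinal MAE), ablation harnesses over loss components and attention
    layer subsets, and attention-map interpretability panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
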