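Package: wsiattn
Title: Attention-Based Classification of High-Resolution Histopathology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weakly supervised classification of high-resolution esophageal
    histopathology tissue images into four classes (normal, Barrett esophagus
    without dysplasia, Barrett esophagus with dysplasia, adenocarcinoma) from
    tissue-level labels alone. Tissues are tiled into a grid of cells, a shared
    convolutional backbone extracts a per-cell feature map, and a 3-D
    convolutional soft-attention module produces per-filter attention maps whose
    affine combinations of cell features feed a linear classifier. Includes the
    full preprocessing pipeline (background removal, tissue separation,
    highest-risk labelling, grid tiling, channel normalization), the training
    recipe (frozen backbone stages, cyclical learning-rate decay, rotation and
    scale augmentation), attention-map rendering and enrichment scoring, a
    region-of-interest sliding-window baseline with heuristic aggregation, a
    one-vs-rest evaluation suite with bootstrap confidence intervals and the
    McNemar-Bowker test, and a deterministic synthetic tissue-image generator so
    the whole pipeline is exercisable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    class,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
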