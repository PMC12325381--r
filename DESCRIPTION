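Package: camodet
Title: Camouflaged-Pest Object Detection Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and detecting camouflaged objects (such as
    locusts and other field pests) in annotated image datasets. Implements the
    Camouflage Degree (CD) statistic based on chi-squared distances between
    foreground and background RGB histograms, COCO-format dataset input/output
    with hold-out splitting, a synthetic camouflage scene generator with a
    tunable foreground-background similarity parameter, copy-paste data
    augmentation, and desk-scale implementations of the computational building
    blocks of a DETR-style camouflage detector: multi-scale deformable
    attention, fine-grained foreground token scoring, a dual-branch soft-mask
    module, denoising queries, DropKey attention regularisation, Hungarian
    set matching, and a composite detection loss, together with a small
    training and evaluation harness (COCO-style average precision, ablation
    runs, activation heatmaps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
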