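Package: octstain
Title: Virtual Histology Staining of Coronary OCT Images with a
    Structure- and Pathology-Aware Transformer GAN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unpaired image-to-image translation between coronary optical
    coherence tomography (OCT) images and hematoxylin-eosin (H&E) histology,
    using a cycle-consistent generative adversarial network whose generators
    combine a U-Net style convolutional multi-scale extractor with windowed
    (Swin-style) self-attention blocks and a transformer encoder-decoder head
    that enforces the three-layer arterial wall structure (intima, media,
    adventitia) and awareness of pathological patterns (lipid pools,
    calcifications). Includes a synthetic coronary phantom generator for
    desk-scale experiments, reference-free set similarity metrics (Frechet
    inception distance and perceptual hash value), reader-study (visual Turing
    test) statistics, slice-by-slice 3D staining, and a small reverse-mode
    automatic differentiation core so the whole model trains on a CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    withr
Config/testthat/edition: 3
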