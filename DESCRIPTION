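Package: slidecarto
Title: Superpixel-Based Whole-Slide Tissue Cartography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dense tissue-class mapping ("cartography") of H&E-stained
    whole-slide histology images. Slides are analysed at a coarse pyramid
    level, converted to stain optical densities by colour deconvolution,
    and partitioned into stain-aware superpixels with a modified SLIC
    clustering in [H, E, x, y] space. A bounded random subset of
    native-resolution image patches per superpixel is classified by a
    pluggable patch classifier; patch softmax vectors are fused into a
    superpixel label with a vote-difference confidence and an optional
    rejection class. From the class map the package derives the tumour
    area (with necrosis/mucus merging and hole filling), IoU/Dice overlap
    against a reference mask, an invasive-margin band, and tumour
    composition ratios. A synthetic phantom generator with exact ground
    truth and a configurable-noise oracle classifier provides a fully
    self-contained test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
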