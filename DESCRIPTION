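Package: limbseg
Title: Muscle Segmentation and DEXA Agreement Analysis for Lower-Limb Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing skeletal muscle mass from standing lower-extremity
    radiographs. Provides a synthetic limb-phantom generator with paired
    DEXA-style lean-mass records, the standard radiograph preprocessing stack
    (intensity scaling, histogram equalization, z-scoring, gamma correction,
    resizing, horizontal-flip augmentation), encoder-decoder segmentation
    networks (U-Net, a 2D V-Net adaptation, and U-Net++) trained with a soft
    Dice loss and AdamW, a multiclass evaluation suite (IoU, Dice, average
    distance, Hausdorff distance, relative absolute area difference with the
    usual empty-mask conventions), pixel-spacing-based region-area
    quantification, and method-agreement statistics against DEXA-derived
    indices (Pearson correlation, ordinary least squares, Bland-Altman limits
    of agreement, paired t-tests, skeletal muscle index).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
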