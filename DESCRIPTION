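Package: morphedge
Title: Self-Adaptive Morphological Edge Detection for Grayscale Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Noise-robust edge detection for 8-bit grayscale images such as
    MRI cross-sections. Implements flat grayscale morphology (erosion,
    dilation, opening, closing) with directional half-line structuring
    elements, the six classical morphological gradient operators, cascaded
    open/close anti-noise gradients and their convex combination, image-driven
    eight-direction structuring-element weights, and a PSNR-gated multiscale
    fusion loop. Ships an MSE/PSNR/SSIM evaluation harness, a seeded synthetic
    phantom generator with exact ground-truth edge maps, and a command-line
    interface for detection, simulation, and evaluation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
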