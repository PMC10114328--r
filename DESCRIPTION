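Package: fundusdr
Title: Diabetic Retinopathy Grading with a Revised ResNet-50 and a Fundus Preprocessing SOP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale diabetic retinopathy (DR) grading stack for fundus
    photographs. Implements a deterministic preprocessing standard operating
    procedure (black-border auto-crop, circular crop, HSV hue/value histogram
    equalization), a three-label image quality gate, a revised ResNet-50 in
    which the outputs of the first two stage-5 residual blocks are merged
    elementwise before a regularized sigmoid head, a reduce-on-plateau
    learning-rate schedule, accuracy and cross-entropy metrics, an activation
    heatmap visualization tool, and a synthetic fundus image generator with
    controllable lesions and quality degradations so the whole pipeline is
    testable without clinical data. The network engine (convolution, batch
    normalization, backpropagation, SGD with momentum) is implemented in
    vectorized base R on top of BLAS matrix products.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    optparse,
    png,
    jpeg,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
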