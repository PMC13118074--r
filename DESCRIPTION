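Package: hsifruit
Title: Hyperspectral Fruit-Defect Segmentation Under Multiple Illumination Modes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pixel-wise defect segmentation of fruit in visible/NIR
    hyperspectral images (450-850 nm) acquired under local, simultaneous, or
    sequential multi-angle illumination. Implements flat-field reflectance
    calibration, constrained specular/diffuse reflectance decomposition from
    multi-angle acquisitions, Otsu-based object-mask extraction, four pixel
    classifiers (spectral angle mapper, random forest, RBF support vector
    machine, and a 1-D convolutional neural network over the spectral axis),
    and a segmentation metric grid (accuracy, error rate, precision, recall,
    specificity, F1, IoU). A seeded synthetic phantom generator produces
    multi-angle hyperspectral scenes with known ground truth so every stage of
    the pipeline can be exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    randomForest,
    e1071,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
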