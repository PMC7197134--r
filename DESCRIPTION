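Package: LesionQuant
Title: Lesion Detection and Quantification on Cleared, Stained Leaves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated detection and quantification of stained lesions on
    transmitted-light images of cleared, trypan-blue-stained leaves.
    Segments the backlit light table and the leaf, reconstructs the
    illumination field and white-balances the image, converts transmission
    to an absorbance-based stain score (blueness times darkness), detects
    lesions down to single-pixel scale with multiscale zero-sum
    center-surround filtering, measures per-lesion morphometrics, computes
    leaf-scale damage, and removes false positives by mini-batch k-means
    feature clustering. Includes a seeded synthetic scene generator with
    full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ImageAnalysis, Segmentation, Classification
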