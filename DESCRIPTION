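Package: kranzvein
Title: Leaf Vein Density Quantification from Starch-Stained Micrographs
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Automated quantification of leaf vein density in C4 plants from
    high-contrast, iodine (starch) stained micrographs. Images are converted to
    greyscale, contrast-enhanced with CLAHE, mean-blurred, binarized with Otsu's
    method and skeletonized; short spur branches are trimmed (with an optional
    automatic trim factor) and, for grass leaves, commissural veins can be
    removed before skeleton pixel counts are converted to vein density in
    micrometres per square millimetre. Includes a batch driver with a deferred
    file-based manual check, a synthetic vein-image generator with exact
    analytic ground truth for end-to-end validation, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
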