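Package: nevuscreen
Title: Benign-First Reverse-Exclusion Screening for Dermoscopic Melanocytic Nevi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for melanoma screening by reverse exclusion: a detector is
    trained to recognise benign melanocytic nevi with high confidence, and any
    lesion it cannot confidently call a nevus is flagged high-risk. The package
    implements the Shape-IoU bounding-box regression loss, a multidimensional
    collaborative attention (MCA) block, a lightweight depthwise-separable
    one-stage detector with dual (one-to-many / one-to-one) label assignment and
    NMS-free inference, detection metrics (precision, recall, mAP), screening
    safety statistics (false-negative rate, exact McNemar tests), a lesion
    boundary morphometrics suite (Zhang-Suen skeletonisation, scale-resolved
    fractal dimension, elliptic Fourier descriptors, radial-distance asymmetry),
    and a synthetic dermoscopic image generator so that the whole pipeline is
    exercisable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
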