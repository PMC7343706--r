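Package: octplaq
Title: Pixel-Wise Atherosclerotic Plaque Tissue Characterization for
    Intravascular OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative tissue characterization of
    atherosclerotic plaque in polar-coordinate intravascular optical
    coherence tomography (OCT) images. Implements dynamic-programming
    lumen segmentation with guide-wire shadow handling, single-scattering
    (Lambert-Beer) attenuation-coefficient inversion with confocal and
    roll-off compensation, a per-pixel texture feature bank (first-order
    statistics, gray-level co-occurrence, neighborhood gray-tone
    difference, differential box-counting fractal signature), random-forest
    pixel classification into fibrous, calcified and lipid tissue, and the
    matching evaluation suite (per-class sensitivity/specificity/accuracy,
    image-grouped cross-validation, ICC, Bland-Altman and regression
    agreement). A forward-model phantom simulator with known tissue maps
    and optical parameters provides ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    randomForest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
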