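Package: pcbp
Title: Phase Congruency Binary Patterns for Ultrasound Texture Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contrast-invariant texture analysis of breast-ultrasound regions of
    interest. Computes oriented phase-congruency maps from a log-Gabor quadrature
    filter bank, encodes them with variance-weighted rotation-invariant uniform
    local binary patterns into the PCBP descriptor, and evaluates benign versus
    malignant discrimination with an RBF-SVM under leave-one-out, bootstrap and
    cross-contrast (contrast-improvement, gamma-correction, histogram-equalization)
    protocols. Includes a deterministic generator of speckle tumor phantoms so the
    whole pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    e1071,
    pROC,
    png,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
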