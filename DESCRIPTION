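Package: glandcell
Title: Gland and Stroma Cell Recognition in Nucleus-Centric Histology Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for recognizing prostatic glandular epithelial cells among
    segmented nuclei in DNA-stained bright-field biopsy images. Provides
    cell-centric patch extraction from nucleus segmentations, a per-biopsy
    appendable container format that can reconstruct the source image,
    a compact VGG-lineage convolutional classifier (GlandNet family) with a
    purpose-built C++ training engine, a two-round false-positive-relabeling
    semi-supervised training procedure for one-sided annotation misses, a
    synthetic gland/stroma tissue generator with known ground truth, and a
    full evaluation suite (confusion ledger, ROC/AUC, PR/AP, prediction
    overlays, observer-consensus selection).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    tiff,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
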