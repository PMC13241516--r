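Package: ceodr
Title: Quantification of Biomolecular Condensates in Extract-in-Oil Droplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify stress-granule-like condensates inside
    cytosolic extract-in-oil droplets (CEODs) imaged by two-channel
    fluorescence microscopy. Provides a synthetic micrograph generator with
    full ground truth, droplet ("mother") and condensate ("child")
    segmentation with rolling-ball background subtraction and parent
    assignment, per-object morphology (area, perimeter, circularity) and
    per-replicate summaries, single-exponential FRAP recovery fitting, and
    light colocalisation and hypergeometric set-overlap statistics. All
    tabular results are tibbles so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
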