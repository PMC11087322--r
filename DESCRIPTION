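Package: haloquant
Title: Quantification of Chromogenic Halo Assays on Agar Plates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies enzymatic activity halos on back-lit agar plate
    photographs from functional screens of clone libraries. Converts 8-bit
    sRGB images to CIELAB (D65, 2 degree observer), segments blue-positive
    pixels by a b* band, detects rounded halo regions with a circularity
    filter, converts pixel counts to physical areas (cm^2) via a drawn-line
    calibration, and organises per-clone areas into a clones-by-conditions
    density matrix with hit-rate summaries and clone ranking. Includes a
    seeded synthetic plate generator with known ground truth for end-to-end
    validation, and small sequence utilities (ORF translation, average
    protein molecular mass).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    jpeg,
    knitr,
    optparse,
    rmarkdown,
    seqinr,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
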