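Package: sealtherm
Title: Automated Detection, Classification and Counting of Seals in
    Thermal Aerial Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and counts hauled-out homeotherms (grey seals) in
    georeferenced single-band thermal rasters from drone surveys.
    Implements temperature thresholding, connected-component extraction of
    warm pixel clusters, polygon attributes (planar area, mean temperature,
    convex-hull solidity), a rule-based classifier separating individual
    young-of-the-year and adult seals from multi-animal aggregations,
    zero-sum high-pass filtering to split aggregations into individuals,
    count summaries, and a point-versus-polygon accuracy assessment against
    human annotations. Includes a seeded synthetic thermal-scene generator
    with ground truth so the full pipeline can be exercised and validated
    without field data, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
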