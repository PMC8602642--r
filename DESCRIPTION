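Package: koscreen
Title: Transposon Knockout-Collection Design, Screening and Bioleaching Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for genome-wide transposon knockout
    collections in acid-producing bacteria: Monte Carlo design of collection
    saturation from TA/AT insertion-site density, combinatorial (Sudoku-style)
    pooling with naive address deconvolution and condensed-collection
    curation, dual colorimetric acidification screens (thymol blue endpoint
    ratio, bromophenol blue kinetic rate) with plate-wise IQR outlier hit
    calling, Bonferroni-corrected proxy-wild-type confirmation statistics,
    one-sided Fisher's exact gene-ontology enrichment, and rare-earth-element
    bioleaching quantification with pH-extraction regression. Includes a
    seeded synthetic-data generator emulating every input so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
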