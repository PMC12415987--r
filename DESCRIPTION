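Package: nucquant
Title: Nuclear Morphometry, Translocation and Foci Quantification for
    Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for chronic-toxicity imaging studies of
    cultured cells: segmentation of DAPI-stained nuclei and GFP-marked cell
    bodies, a vehicle-referenced classifier for giant and multinucleated
    cells based on total nuclear area and perimeter (mean + 3 SD rule with
    per-cell summation over nuclei), nuclear-to-cytosolic marker
    translocation ratios, Laplacian-of-Gaussian foci counting, and the
    downstream tabular statistics (2^-ddCt relative expression,
    Benjamini-Hochberg step-up, a CPM/FDR/fold-change differential
    expression filter, cytokine normalization and unit conversion). A
    synthetic-microscopy generator renders ground-truthed multi-channel
    scenes so every stage is benchmarked against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    methods,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
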