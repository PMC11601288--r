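Package: spotsplitr
Title: Same-Section Integration of Spatial Transcriptome Spots with
    Single-Cell Protein Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates microfluidic deterministically barcoded spatial
    transcriptomics (DBiT-seq) spot data with same-section multiplexed
    protein imaging (CODEX). Provides per-cell feature extraction and
    quantile scaling from segmentation masks, binary-mask similarity
    registration of the imaging frame onto the barcoded spot grid,
    cell-to-spot assignment and per-spot cell-type composition,
    reference-guided splitting of each spot into pure-cell-type sub-spots
    with matched protein aggregates, pivot-seeded label transfer by a
    linear support vector machine, spatially binned cross-section
    correlation quality control, and a synthetic paired-data simulator
    with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite,
    tiff,
    EBImage,
    e1071,
    withr,
    generics,
    digest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
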