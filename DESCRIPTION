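Package: fishcount
Title: Cell Type-Specific Single-Molecule RNA Quantification from 3D
    Fluorescence Stacks
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies single-molecule FISH (smFISH/RNAscope) transcripts
    per nucleus or cell from multi-channel 3D fluorescence stacks and assigns
    each nucleus a cell type from immunostaining channels.  The pipeline
    band-pass filters transcript channels, detects diffraction-limited spots
    by 3D Gaussian fitting with an integrated-intensity (min_mass) gate,
    segments nuclei by watershed with depth-controlled basin merging,
    minimum-size filtering and ID-based manual correction, assigns nuclei to
    marker-positive cell types, and writes batch results, QC images and a
    reloadable run-metadata file.  A synthetic-experiment generator with full
    ground truth supports validation without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    minpack.lm,
    png,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
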