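Package: cyclegate
Title: High-Content Imaging Cell-Cycle Analysis by DNA-Content Gating
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An open image-cytometry pipeline for multiparametric cell-cycle
    analysis of multichannel fluorescence plate images: nuclear segmentation
    with two splitting presets, singlet/multiplet discrimination by a trainable
    linear classifier on nuclear morphology, normalisation of integrated DNA
    intensity to the G1 peak, rectangular gating into cell-cycle phases
    (DNA-only and DNA+EdU+pHH3 modes, with Ki67-based G0 and marker-positive
    subpopulations), and estimation of S-phase duration and population doubling
    time from EdU/BrdU dual-pulse counts.  A synthetic plate simulator with
    per-nucleus ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
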