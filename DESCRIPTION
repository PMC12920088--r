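Package: fulmr
Title: Functional Ultrasound Localization Microscopy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for transcranial functional ultrasound
    localization microscopy (fULM) of the cortical microvasculature.
    Provides singular-value-decomposition clutter filtering of ultrafast
    compound frame stacks, subpixel microbubble localization and tracking,
    super-resolved microbubble flow, velocity and backscatter mapping,
    vessel segmentation with diameter and tortuosity quantification,
    power-Doppler haemodynamic response analysis, and microscopic
    activation mapping of stimulus-evoked functional hyperaemia, together
    with a ground-truthed synthetic ultrafast-movie generator for
    validation.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
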