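Package: barrelquant
Title: Quantification of Barrel-Cortex Imaging, Tracing and Behavior Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy analysis pipelines for mouse barrel-cortex experiments:
    widefield calcium-imaging response metrics with dual-wavelength
    hemodynamic correction, binned intensity profiling of section images
    (cortical-depth and barrel-row profiles, log2 fold-changes, c-fos
    ratios), monosynaptic rabies-tracing connectivity indices, laser
    photostimulation input maps, a novel-texture-discrimination behavioral
    index, and random-intercept mixed models with parametric-bootstrap
    tests for animal-clustered outcomes. A companion simulation module
    generates every input with known ground truth so each pipeline can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
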