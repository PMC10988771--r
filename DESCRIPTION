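Package: gliocircuit
Title: Multimodal Mapping of Cognitive Circuits in Tumour-Infiltrated Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing whether glioma-infiltrated cortex participates in
    large-scale cognitive circuits. Implements intraoperative electrocorticography
    band-power contrasts with a loop-rotation permutation test, seed-based
    resting-state functional connectivity with a spherical spin permutation test
    for network co-localisation, tumour-network connectivity statistics with
    Bonferroni family-wise error control, and mixed-effects and linear models
    linking connectivity to task responses and longitudinal cognitive outcomes.
    Includes synthetic-data generators with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    RNifti,
    lme4,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
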