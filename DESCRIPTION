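Package: gapforest
Title: Individual-Based Forest Gap Modelling of Tropical Montane Carbon Balance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-based forest gap model for tropical montane stands,
    with trait-based plant functional type (PFT) classification of stem
    censuses, patch-based canopy light competition (Lambert-Beer extinction),
    per-tree carbon-balance growth, stochastic mortality and light-gated
    recruitment, three-pool ecosystem carbon accounting with net ecosystem
    exchange, and inverse calibration of growth and mortality parameters
    against field biomass. Includes a synthetic census generator emulating a
    lower montane forest inventory so the full pipeline runs without field
    data files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
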