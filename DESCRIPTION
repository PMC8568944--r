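Package: airmorph
Title: Airway Morphometry, Lung Mechanics and Cohort Genetics for
    COPD-Like Lesion Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native toolkit for quantifying chronic obstructive
    pulmonary disease (COPD)-like lesions in airway tissue and for the
    companion statistical analyses. Implements saturation-based airspace
    segmentation of lung-parenchyma micrographs with particle statistics and
    the mean linear intercept (MLI), epithelium mean-height morphometry,
    Salazar-Knowles exponential fitting of pressure-volume deflation limbs
    with static compliance, a nasal-polyp cohort pipeline (exclusion filters,
    outcome binarization, univariate screening, multivariate logistic
    regression with odds ratios), in-silico TaqI restriction-fragment
    genotyping of the CHRNA5 rs16969968 polymorphism, and small assay
    calculators (calcium F/Fmax, 2^-ddCt fold change, MTT proliferation
    index, protein-normalized cytokines). A synthetic-data module generates
    every input with known ground truth so the full pipeline is testable
    without raw images or patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml,
    EBImage
Suggests:
    Biostrings,
    png,
    testthat (>= 3.0.0),
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
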