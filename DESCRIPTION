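Package: bryoclim
Title: Ensemble Species Distribution Modelling of Island Endemics Under
    Climate Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ensemble species-distribution-modelling pipeline for
    projecting climate-driven range change of island endemic species,
    built around the workflow used for Macaronesian endemic bryophytes:
    occurrence grid-thinning and minimum-record filtering, collinearity
    screening of bioclimatic predictors, three modelling techniques
    (climatic envelope, penalized presence-background regression, random
    forest) evaluated by repeated 70/30 splits with AUC and TSS quality
    control, an AUC-weighted consensus, multivariate environmental
    similarity (MESS) masking of non-analog climates, sensitivity-based
    binarization, and downstream range-change statistics: percent
    suitable area remaining, threat-status classification, elevational
    shifts with paired t-tests, archipelago comparisons by
    Kruskal-Wallis with Nemenyi post-hoc tests, and protected-area
    coverage. A synthetic-landscape generator provides spatially
    autocorrelated climate surfaces, virtual species, presence-only
    samples, climate-change scenarios and protected-area polygons so the
    whole pipeline is testable without external data.
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
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
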