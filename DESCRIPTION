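Package: eptr
Title: Ensemble Distribution and Richness Models for Riverine EPT Insects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ensemble species distribution models (binomial GLM and random
    forest, AUC-weighted) and macroecological richness models (Poisson GLM
    and random forest, Spearman-weighted) for Ephemeroptera, Plecoptera and
    Trichoptera (EPT) communities in running waters, with stacked-SDM
    richness via the exact Poisson-binomial distribution, spatial eigenvector
    covariates from a doubly centered distance matrix (exact and Nystrom
    approximation), survey completeness filtering, climate-scenario
    projection of occurrence probability and richness, and a synthetic
    riverscape and virtual-species generator for testing the full pipeline
    with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    lme4
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
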