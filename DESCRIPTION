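Package: hybridgp
Title: Genomic Prediction and Heterotic-Pattern Analysis for Hybrid Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for genomic selection in hybrid crop
    breeding programs. Builds in-silico hybrid genotypes from inbred parent
    lines, filters markers, estimates SNP heritability by Haseman-Elston
    regression and single-component REML, fits ridge-regression BLUP
    (rrBLUP) and its Haseman-Elston variant (HEBLP|A) alongside random-forest
    and gradient-boosted-tree baselines, evaluates prediction accuracy under
    repeated train/candidate splits, predicts genomic estimated breeding
    values (GEBVs) for every cross of a half-diallel, and summarises general
    combining ability and heterotic patterns over germplasm groups. Includes
    a synthetic breeding-population simulator with full ground truth for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
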