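Package: hdcohort
Title: Longitudinal Huntington's Disease Cohort Preprocessing, Imputation
    and Prognosis Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, tested workflow for Enroll-HD-shaped
    longitudinal clinical cohorts in Huntington's disease (HD):
    a synthetic-cohort generator with known ground truth and explicit
    structural-missingness mechanisms; rule-based pre-processing
    (cohort inclusion, variable filtering, outlier flagging, derived
    variables such as the CAG-age product, deterministic inference of
    structurally missing values, symptom-onset filtering, one-hot
    encoding); a score-ordered machine-learning imputation cascade with
    cross-validated per-variable model selection; age-at-onset
    prediction benchmarked against the Langbehn exponential formula on
    narrow and wide CAG-repeat ranges; and a masked two-head gated
    recurrent unit (GRU) classifier of current and next-year driving
    capability with calibration bands and personalised trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils,
    generics,
    ranger,
    minpack.lm,
    xgboost,
    nnet,
    caret,
    e1071
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
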