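Package: aucselect
Title: Simultaneous Nonparametric AUC Inference for Biomarker Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects promising diagnostic tests (biomarkers) in early
    diagnostic trials by nonparametric simultaneous one-sided inference on
    the areas under the ROC curves (AUCs) of several markers measured on
    the same subjects. Implements midrank/placement estimators of the AUC
    vector and its covariance, multiple contrast tests with equicoordinate
    multivariate-normal quantiles, logit-transformed simultaneous
    confidence bounds, and a Wild Bootstrap small-sample approximation of
    the joint null distribution, together with a Monte-Carlo engine for
    familywise type-I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    mvtnorm,
    readr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
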