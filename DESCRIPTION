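Package: navsdoh
Title: Predicting Social Determinants of Health from Patient Navigation Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting patients' social determinants of health
    (SDoHs) from patient-navigation tracking logs. Implements six
    longitudinal data-preparation strategies that turn encounter histories
    into labelled instances, latent Dirichlet allocation topic features for
    navigator notes, a cross-validated multi-algorithm classifier grid with
    confusion-row composition and grouped-confidence statistics, two-site
    codebook harmonization with encounter-intensity binning and travel-time
    augmentation, and a compact 1D convolutional network for multi-label
    SDoH prediction. A synthetic two-site cohort generator with known
    ground truth makes every stage testable without access to protected
    study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
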