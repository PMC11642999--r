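Package: openmosq
Title: Open-Set Mosquito Species Classification with OpenMax and Weibull Tail Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for open-set recognition on top of any closed-set
    classifier, developed around mosquito species identification. Builds
    per-class mean activation vectors and Weibull models of within-class
    distance tails from activation (logit) tables, recalibrates scores via
    the Weibull survival function, and classifies samples into known classes
    or an explicit "unknown" class by either a max-score threshold rule or
    the OpenMax probability procedure. Also provides the surrounding
    dataset-engineering stages (perceptual-hash deduplication, stratified
    train/validation/test splitting, class-balancing augmentation), a full
    evaluation battery over known-plus-unknown label sets (confusion
    matrices, macro/weighted metrics, MCC, balanced accuracy, ROC/PR curves,
    threshold sweeps), and synthetic activation and image generators so the
    entire pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    fitdistrplus,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
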