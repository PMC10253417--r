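Package: aepscatter
Title: Tinnitus Distress Classification from Auditory Evoked Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for classifying
    tinnitus-related distress from auditory evoked potentials (auditory
    brainstem responses and auditory middle latency responses) together with
    clinical covariates. Provides waveform input/output in a documented XML
    dialect and CSV, a synthetic cohort generator with controllable group
    effects, automated peak/trough annotation with latency and amplitude
    extraction, the Levene/t-test/Cohen's d group-comparison workflow with
    THI-based grouping and gender-by-hearing stratification, a from-scratch
    second-order wavelet time scattering transform with Morlet filter banks,
    cross-validated LASSO selection of clinical features, and a multi-model
    cross-validated classification benchmark reporting AUC, sensitivity and
    specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    MASS,
    nnet,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
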