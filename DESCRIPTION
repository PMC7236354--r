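Package: icatest
Title: Rapid Visual Categorization Testing, Scoring and Cognitive-Impairment Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for building and analysing a five-minute rapid visual
    categorization test of information processing speed (animal versus
    non-animal images under backward masking). Generates spatial-frequency
    filtered binary noise masks and procedural stimulus sets, schedules and
    persists test sessions, scores them (accuracy, an exponential speed
    transform of correct reaction times, and their composite), removes
    reaction-time outliers with Tukey fences, classifies cognitive impairment
    with an L2-regularized multinomial logistic regression evaluated by
    leave-one-out cross-validation and ROC analysis, and provides the
    psychometric statistics used to validate such tests (norm-based
    impairment labelling, Cohen's d, test-retest reliability, composite
    z-scores). A calibrated synthetic-cohort simulator makes the whole
    pipeline runnable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    EBImage
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
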