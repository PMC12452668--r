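Package: pfedme
Title: Paraconsistent Feature Engineering and Classifier Benchmarking for
    Diabetic Macular Edema Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tabular pre-diagnosis of diabetic macular edema (DME)
    from quantitative optical coherence tomography (OCT) features.  Implements
    paraconsistent feature engineering (PFE): every candidate feature is scored
    by an intraclass-similarity degree (alpha) and an interclass-overlap degree
    (beta), mapped to the paraconsistent plane via the degree of certainty
    G1 = alpha - beta and the degree of contradiction G2 = alpha + beta - 1,
    and ranked by distance to the ideal point (1, 0).  A benchmarking harness
    trains logistic regression, support vector machine, k-nearest-neighbour
    and decision-tree classifiers on the full 24-feature ETDRS macular grid
    panel and on the PFE-selected subset, in binary (DME yes/no) and six-class
    phenotype scenarios, and evaluates them with a diagnostic metric suite
    (confusion matrix, sensitivity, specificity, PPV, NPV, F1, rank-sum ROC
    AUC, micro-average one-vs-rest AUC) implemented from first principles.
    A synthetic cohort generator with configurable class-conditional effect
    sizes emulates the feature table so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    caret,
    e1071,
    ggplot2,
    jsonlite,
    nnet,
    rlang,
    rpart,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
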