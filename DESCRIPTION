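Package: morphonode
Title: Morphonode Predictive Model for Inguinal Lymph-Node Ultrasound Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-modular machine-learning model that classifies inguinal
    lymph-node ultrasound profiles as metastatic or non-metastatic in vulvar
    cancer patients. Combines a five-member random-forest majority-vote
    ensemble trained by nested cross-validation, a binomial regression risk
    estimator with F1-maximizing and joint sensitivity/specificity risk
    thresholds, Gini decision-tree metastatic-risk signatures with a
    marker-based screen, a parametric logistic-loss prediction-error
    estimate, and cosine-similarity profiling against a reference cohort.
    Includes a calibrated synthetic-cohort generator for training and
    validation at desk scale, missing-value imputation (LASSO for continuous
    features, classification trees for categorical features), and the
    diagnostic performance statistics (confidence intervals, ROC analysis,
    two-proportion tests with continuity correction, Wilcoxon shift
    estimates) used to evaluate the model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    rpart,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
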