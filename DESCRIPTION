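Package: dissoscreen
Title: Three-Channel Dissociation Screening for Early Cognitive Impairment from Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores transcribed spoken phrases on three affective channels --
    dictionary-based sentiment polarity (signed strength -5..5 with booster and
    negation rules), SO-PMI semantic orientation against the seed words
    "excellent" and "poor" over a local reference corpus, and a trinary tone-of-voice
    band derived from speech-emotion labels -- then quantifies cross-channel
    dissociation per diagnostic group with Pearson chi-square tests and runs a
    feature-ablation classification study (decision tree, multilayer perceptron,
    naive Bayes, support vector machine) under stratified 10-fold
    cross-validation with ROC analysis. Includes a synthetic phrase-corpus
    generator that emulates the concordant-control / decoupled-case structure
    the screening procedure assumes, so the whole pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
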