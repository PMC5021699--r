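test_that("the training table carries the four-column record per phrase", {
  scored <- tibble::tibble(
    phrase_id = c("a", "b", "c"),
    class = c("control", "case", "case"),
    polarity = c(3L, 5L, -3L),
    so_code = c(1L, -1L, 1L),
    tone_code = c(1L, -1L, 0L)
  )
  tr <- build_training_file(scored)
  expect_identical(tr$class, c("control", "case", "case"))
  expect_identical(tr$polarity[1], 3L)
  # a record whose polarity sign disagrees with both codes still parses
  expect_identical(unlist(tr[2, c("polarity", "so_code", "tone_code")],
                          use.names = FALSE), c(5L, -1L, -1L))
  expect_identical(nrow(build_training_file(scored[0, ])), 0L)
})

test_that("missing channels and out-of-domain values are rejected by name", {
  bad <- tibble::tibble(phrase_id = c("p1", "p2"), class = "case",
                        polarity = c(3L, NA), so_code = 1L, tone_code = 0L)
  expect_error(build_training_file(bad), "p2")
  expect_error(build_training_file(tibble::tibble(class = "x", polarity = 0L,
                                                  so_code = 0L, tone_code = 0L)),
               "polarity")
  expect_error(build_training_file(tibble::tibble(class = "x", polarity = 2L,
                                                  so_code = 2L, tone_code = 0L)),
               "so_code")
  expect_error(build_training_file(tibble::tibble(class = "x", polarity = 1L)),
               "missing channel")
})

test_that("training files round-trip through the four-column CSV layout", {
  recs <- alzheimer_rows()
  recs$class[1:4] <- "control"
  path <- withr::local_tempfile(fileext = ".csv")
  write_training_file(recs, path)
  expect_identical(readLines(path, n = 1), "class,polarity,pmi,emotion")
  back <- read_training_file(path)
  expect_identical(back, recs)
})

test_that("all four families are perfect on perfectly separable records", {
  recs <- dplyr::bind_rows(
    tibble::tibble(class = "control", polarity = 3L, so_code = 1L, tone_code = 1L)[rep(1, 40), ],
    tibble::tibble(class = "case", polarity = -3L, so_code = -1L, tone_code = 1L)[rep(1, 40), ]
  )
  for (cl in c("decision_tree", "multilayer_perceptron", "bayes_net", "svm")) {
    m <- cross_validate(recs, c("polarity", "so_code", "tone_code"), cl,
                        folds = 5, seed = 9)
    expect_equal(m$precision, 1, info = cl)
    expect_equal(m$recall, 1, info = cl)
    expect_equal(m$f1, 1, info = cl)
    expect_equal(m$roc_auc, 1, info = cl)
  }
})

test_that("label-permuted data scores at chance on average", {
  ds <- generate_dataset(synth_config(n_control_interviews = 2,
                                      n_case_interviews = 2,
                                      phrases_per_interview = 100,
                                      seed = 31), text = FALSE)
  recs <- as_training_records(ds)
  aucs <- sapply(1:10, function(s) {
    set.seed(s)
    shuffled <- dplyr::mutate(recs, class = sample(class))
    cross_validate(shuffled, "polarity", "bayes_net", folds = 5, seed = s)$roc_auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("trapezoid AUC equals the rank-statistic formulation", {
  set.seed(17)
  for (i in 1:20) {
    n <- 60
    truth <- stats::runif(n) < 0.4
    truth[1:2] <- c(TRUE, FALSE)
    score <- stats::rnorm(n) + truth
    if (i %% 2 == 0) score <- round(score)  # exercise heavy ties
    roc <- roc_points(score, truth)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_identical(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
    expect_identical(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
    # Mann-Whitney formulation with ties counted half
    r <- rank(score)
    n1 <- sum(truth); n0 <- sum(!truth)
    auc_rank <- (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    expect_equal(trapezoid_auc(roc), auc_rank, tolerance = 1e-9)
  }
})

test_that("ROC/AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  truth <- stats::runif(80) < 0.5
  truth[1:2] <- c(TRUE, FALSE)
  score <- stats::rnorm(80) + 0.8 * truth
  ours <- trapezoid_auc(roc_points(score, truth))
  ref <- as.numeric(pROC::auc(pROC::roc(response = truth, predictor = score,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("the ablation study covers 7 x 4 models deterministically", {
  ds <- generate_dataset(synth_config(n_control_interviews = 3,
                                      n_case_interviews = 2,
                                      phrases_per_interview = 40,
                                      seed = 51), text = FALSE)
  recs <- as_training_records(ds)
  ab1 <- ablation_study(recs, folds = 5, seed = 4)
  expect_identical(nrow(ab1$metrics), 28L)
  expect_identical(length(unique(ab1$metrics$feature_set)), 7L)
  ab2 <- ablation_study(recs, folds = 5, seed = 4)
  expect_identical(tidy(ab1), tidy(ab2))
  # f1 consistency on every emitted row
  with(ab1$metrics, {
    both <- precision > 0 & recall > 0
    expect_equal(f1[both],
                 2 * precision[both] * recall[both] / (precision + recall)[both])
    expect_true(all(f1[!both] == 0))
  })
  expect_s3_class(autoplot(ab1), "ggplot")
  expect_identical(glance(ab1)$n_models, 28L)
})

test_that("metrics are invariant to shuffling the input records", {
  ds <- generate_dataset(synth_config(n_control_interviews = 2,
                                      n_case_interviews = 2,
                                      phrases_per_interview = 60,
                                      seed = 61), text = FALSE)
  recs <- as_training_records(ds)[, c("class", "polarity", "so_code", "tone_code")]
  set.seed(99)
  shuffled <- recs[sample(nrow(recs)), ]
  for (cl in c("bayes_net", "decision_tree")) {
    m1 <- cross_validate(recs, c("polarity", "so_code"), cl, folds = 5, seed = 2)
    m2 <- cross_validate(shuffled, c("polarity", "so_code"), cl, folds = 5, seed = 2)
    expect_equal(m1[c("precision", "recall", "f1", "roc_auc")],
                 m2[c("precision", "recall", "f1", "roc_auc")])
  }
})

test_that("grouped cross-validation holds whole interviews out together", {
  ds <- generate_dataset(synth_config(n_control_interviews = 6,
                                      n_case_interviews = 6,
                                      phrases_per_interview = 20,
                                      seed = 71), text = FALSE)
  recs <- as_training_records(ds)
  groups <- ds$phrases$interview_id
  m <- cross_validate(recs, c("polarity", "so_code", "tone_code"), "bayes_net",
                      folds = 3, seed = 8, groups = groups)
  expect_true(m$roc_auc >= 0 && m$roc_auc <= 1)
  expect_error(
    cross_validate(recs, "polarity", "bayes_net", folds = 10, seed = 8,
                   groups = groups),
    "at least 10 groups"
  )
})

test_that("degenerate single-class input is refused", {
  recs <- tibble::tibble(class = "case", polarity = rep(c(2L, -2L), 20),
                         so_code = 0L, tone_code = 0L)
  expect_error(cross_validate(recs, "polarity", "bayes_net"), "2 classes")
})
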