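#' Build the per-phrase training table
#'
#' Joins the three channel outputs into the classifier input: one record per
#' phrase with the diagnostic class, the signed polarity strength (-5..-1 or
#' 1..5), the semantic-orientation code and the tone band. This is the
#' four-column training-file layout the screening procedure feeds to its
#' classifiers.
#'
#' @param scored_phrases Data frame carrying `class`, `polarity`, `so_code`
#'   and `tone_code` for every phrase (the result of piping a phrase table
#'   through [score_phrases()], [orient_phrases()] and [band_tone()]);
#'   `phrase_id` and `polarity_label` are carried through when present.
#' @return A tibble with columns `class`, `polarity`, `so_code`, `tone_code`
#'   (plus `phrase_id` / `polarity_label` if supplied), in input order.
#' @export
build_training_file <- function(scored_phrases) {
  df <- tibble::as_tibble(scored_phrases)
  needed <- c("class", "polarity", "so_code", "tone_code")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing channel column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  incomplete <- !stats::complete.cases(df[needed])
  if (any(incomplete)) {
    ids <- if ("phrase_id" %in% names(df)) df$phrase_id[incomplete] else which(incomplete)
    stop(sprintf("phrase(s) %s are missing a channel value",
                 paste(utils::head(ids, 5), collapse = ", ")), call. = FALSE)
  }
  if (any(df$polarity == 0 | abs(df$polarity) > 5)) {
    stop("polarity must be a nonzero integer in [-5, 5]", call. = FALSE)
  }
  if (any(!df$so_code %in% -1:1) || any(!df$tone_code %in% -1:1)) {
    stop("so_code and tone_code must be -1, 0 or +1", call. = FALSE)
  }
  keep <- intersect(c("phrase_id", "class", "polarity", "polarity_label",
                      "so_code", "tone_code"), names(df))
  out <- df[keep]
  out$class <- as.character(out$class)
  out$polarity <- as.integer(out$polarity)
  out$so_code <- as.integer(out$so_code)
  out$tone_code <- as.integer(out$tone_code)
  out
}

#' Read/write a training file in the four-column CSV layout
#'
#' The on-disk layout uses the classical column names
#' `class,polarity,pmi,emotion` (the PMI column is the semantic-orientation
#' code, the emotion column the tone band); in memory the columns are named
#' `class`, `polarity`, `so_code`, `tone_code`. Writing then reading
#' round-trips exactly.
#'
#' @param records Training tibble as returned by [build_training_file()].
#' @param path File path.
#' @return `read_training_file()` returns the training tibble;
#'   `write_training_file()` returns `path` invisibly.
#' @export
write_training_file <- function(records, path) {
  records <- build_training_file(records)
  out <- tibble::tibble(class = records$class, polarity = records$polarity,
                        pmi = records$so_code, emotion = records$tone_code)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_training_file
#' @export
read_training_file <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    class = readr::col_character(), polarity = readr::col_integer(),
    pmi = readr::col_integer(), emotion = readr::col_integer()
  ))
  build_training_file(tibble::tibble(class = df$class, polarity = df$polarity,
                                     so_code = df$pmi, tone_code = df$emotion))
}

classifier_families <- c("decision_tree", "multilayer_perceptron", "bayes_net", "svm")
channel_features <- c("polarity", "so_code", "tone_code")

#' Default classifier hyperparameters
#'
#' The pinned settings echoed into every metrics report: library defaults
#' except where a value is mandatory (the perceptron's hidden-layer size) or
#' needed for well-defined behaviour on sparse factor cells (naive-Bayes
#' Laplace smoothing).
#' @return Named list, one entry per classifier family.
#' @export
classifier_config <- function() {
  list(
    decision_tree = list(engine = "rpart", method = "class", cp = 0.01, minsplit = 20),
    multilayer_perceptron = list(engine = "nnet", size = 5, decay = 0.01,
                                 maxit = 200, entropy = TRUE),
    bayes_net = list(engine = "e1071::naiveBayes", note = "naive Bayes over discrete features",
                     laplace = 1),
    svm = list(engine = "e1071::svm", kernel = "radial", cost = 1,
               scores = "decision values, min-max scaled")
  )
}

# Fold assignment is computed on a canonical ordering of the records (class,
# then feature values), so it depends only on the record multiset and the
# seed: shuffling the input rows cannot change the per-fold multisets or the
# pooled metrics. With `groups` (e.g. interview ids), whole groups are
# assigned to folds instead, stratified by the group's class.
stratified_folds <- function(records, folds, seed, groups = NULL) {
  class <- records$class
  if (is.null(groups)) {
    ord <- order(class, records$polarity, records$so_code, records$tone_code)
    if (min(table(class)) < folds) {
      stop(sprintf("each class needs at least %d records for %d-fold stratified CV",
                   folds, folds), call. = FALSE)
    }
    fold_sorted <- integer(length(class))
    set.seed(seed)
    for (cl in levels(class)) {
      pos <- which(class[ord] == cl)
      fold_sorted[sample(pos)] <- rep_len(seq_len(folds), length(pos))
    }
    fold <- integer(length(class))
    fold[ord] <- fold_sorted
    return(fold)
  }
  grp <- tapply(as.character(class), groups, function(x) x[1])
  if (min(table(grp)) < folds) {
    stop(sprintf("each class needs at least %d groups for %d-fold grouped CV",
                 folds, folds), call. = FALSE)
  }
  gnames <- sort(names(grp))
  gfold <- integer(length(gnames))
  set.seed(seed)
  for (cl in unique(grp)) {
    pos <- which(grp[gnames] == cl)
    gfold[sample(pos)] <- rep_len(seq_len(folds), length(pos))
  }
  gfold[match(as.character(groups), gnames)]
}

fit_and_score <- function(train, test, features, classifier, positive, fit_seed) {
  fml <- stats::as.formula(paste("class ~", paste(features, collapse = " + ")))
  switch(classifier,
    decision_tree = {
      fit <- rpart::rpart(fml, data = train, method = "class")
      list(score = stats::predict(fit, test, type = "prob")[, positive],
           pred = as.character(stats::predict(fit, test, type = "class")))
    },
    multilayer_perceptron = {
      set.seed(fit_seed)
      fit <- nnet::nnet(fml, data = train, size = 5, decay = 0.01, maxit = 200,
                        trace = FALSE)
      raw <- as.numeric(stats::predict(fit, test, type = "raw"))
      # nnet's single output unit models the second factor level
      p_pos <- if (levels(train$class)[2] == positive) raw else 1 - raw
      list(score = p_pos, pred = ifelse(p_pos >= 0.5, positive,
                                        setdiff(levels(train$class), positive)))
    },
    bayes_net = {
      tr <- train; te <- test
      for (f in features) {
        lv <- feature_levels(f)
        tr[[f]] <- factor(tr[[f]], levels = lv)
        te[[f]] <- factor(te[[f]], levels = lv)
      }
      fit <- e1071::naiveBayes(fml, data = tr, laplace = 1)
      list(score = stats::predict(fit, te, type = "raw")[, positive],
           pred = as.character(stats::predict(fit, te, type = "class")))
    },
    svm = {
      fit <- suppressWarnings(  # constant features trip libsvm's scaling note
        e1071::svm(fml, data = train, kernel = "radial", cost = 1,
                   decision.values = TRUE)
      )
      pr <- stats::predict(fit, test, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # libsvm labels the decision values "A/B": positive values favour A
      first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
      score <- if (first == positive) dv[, 1] else -dv[, 1]
      list(score = as.numeric(score), pred = as.character(pr))
    },
    stop(sprintf("unknown classifier '%s'", classifier), call. = FALSE)
  )
}

feature_levels <- function(feature) {
  if (feature == "polarity") c(-5:-1, 1:5) else -1:1
}

#' Cross-validated metrics for one feature set and classifier family
#'
#' Stratified k-fold cross-validation on the training table: the model is fit
#' on k-1 folds, scored on the held-out fold, and precision, recall, F1 and
#' ROC AUC are computed on the pooled out-of-fold predictions with the `case`
#' group as the positive class. Classifier families are realized by standard
#' engines (rpart, nnet, e1071) with the settings of [classifier_config()].
#'
#' @param records Training tibble (see [build_training_file()]); exactly two
#'   classes.
#' @param features Non-empty subset of `c("polarity", "so_code", "tone_code")`.
#' @param classifier One of `"decision_tree"`, `"multilayer_perceptron"`,
#'   `"bayes_net"`, `"svm"`.
#' @param folds Number of stratified folds (default 10).
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   fitting; fixing it makes the result fully reproducible.
#' @param positive Positive class label for the metrics (default `"case"`; if
#'   absent, the lexicographically last class).
#' @param groups Optional vector (one per record, e.g. interview ids) for
#'   grouped cross-validation: whole groups are held out together, which
#'   avoids leaking speaker identity across folds. The default (NULL) pools
#'   phrases as independent units.
#' @return One-row tibble with `feature_set`, `classifier`, `precision`,
#'   `recall`, `f1`, `roc_auc`, and a `roc` list-column holding the ordered
#'   (fpr, tpr) points of the ROC curve.
#' @export
cross_validate <- function(records, features, classifier, folds = 10, seed = 1,
                           positive = "case", groups = NULL) {
  records <- build_training_file(records)
  features <- match.arg(features, channel_features, several.ok = TRUE)
  classifier <- match.arg(classifier, classifier_families)
  classes <- sort(unique(records$class))
  if (length(classes) != 2) {
    stop(sprintf("classification needs exactly 2 classes, got %d", length(classes)),
         call. = FALSE)
  }
  if (!positive %in% classes) positive <- classes[length(classes)]
  records$class <- factor(records$class, levels = c(setdiff(classes, positive), positive))

  fold <- stratified_folds(records, folds, seed, groups = groups)
  set.seed(seed)
  fit_seeds <- sample.int(.Machine$integer.max, folds)

  score <- numeric(nrow(records))
  pred <- character(nrow(records))
  for (k in seq_len(folds)) {
    test_idx <- which(fold == k)
    out <- fit_and_score(records[fold != k, , drop = FALSE],
                         records[test_idx, , drop = FALSE],
                         features, classifier, positive, fit_seeds[k])
    score[test_idx] <- out$score
    pred[test_idx] <- out$pred
  }
  if (classifier == "svm") score <- minmax_scale(score)

  truth <- records$class == positive
  predicted <- pred == positive
  tp <- sum(truth & predicted); fp <- sum(!truth & predicted); fn <- sum(truth & !predicted)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  roc <- roc_points(score, truth)

  tibble::tibble(
    feature_set = paste(features, collapse = "+"),
    classifier = classifier,
    precision = precision, recall = recall, f1 = f1,
    roc_auc = trapezoid_auc(roc),
    roc = list(roc)
  )
}

minmax_scale <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' ROC curve points from scores and binary truth
#'
#' Sweeps the decision threshold over the distinct score values (ties grouped)
#' and records (false-positive rate, true-positive rate) pairs, starting at
#' (0, 0) and ending at (1, 1), nondecreasing in both coordinates.
#'
#' @param score Numeric vector; larger means more case-like.
#' @param truth Logical vector, TRUE for the positive class.
#' @return Tibble with columns `fpr` and `tpr`.
#' @export
roc_points <- function(score, truth) {
  stopifnot(length(score) == length(truth), any(truth), any(!truth))
  ord <- order(score, decreasing = TRUE)
  score <- score[ord]; truth <- truth[ord]
  tp <- cumsum(truth); fp <- cumsum(!truth)
  last <- c(score[-1] != score[-length(score)], TRUE)  # keep one point per tie group
  tibble::tibble(
    fpr = c(0, fp[last] / sum(!truth)),
    tpr = c(0, tp[last] / sum(truth))
  )
}

#' @rdname roc_points
#' @param roc A tibble of ROC points.
#' @return `trapezoid_auc()` returns the area under the curve.
#' @export
trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Feature-ablation classification study
#'
#' Runs [cross_validate()] over all 7 non-empty subsets of the three channels
#' crossed with the four classifier families (28 rows), with a shared fold
#' assignment so rows are comparable. This is the screening study's ablation:
#' single channels are weak, and combining all three is where the
#' dissociation signal becomes classifiable.
#'
#' @inheritParams cross_validate
#' @return Object of class `ablation_report`: tibble `metrics` (28 rows), the
#'   pinned `config` from [classifier_config()], `folds`, `seed` and
#'   `positive`.
#' @export
ablation_study <- function(records, folds = 10, seed = 1, positive = "case") {
  subsets <- unlist(lapply(1:3, function(k) {
    asplit(utils::combn(channel_features, k), 2)
  }), recursive = FALSE)
  metrics <- purrr::map_dfr(subsets, function(fs) {
    purrr::map_dfr(classifier_families, function(cl) {
      cross_validate(records, features = as.character(fs), classifier = cl,
                     folds = folds, seed = seed, positive = positive)
    })
  })
  structure(
    list(metrics = metrics, config = classifier_config(), folds = folds,
         seed = seed, positive = positive),
    class = "ablation_report"
  )
}

#' @export
print.ablation_report <- function(x, ...) {
  cat(sprintf("Ablation study: %d-fold stratified CV, positive class '%s', seed %d\n\n",
              x$folds, x$positive, x$seed))
  df <- dplyr::select(x$metrics, "feature_set", "classifier", "precision",
                      "recall", "f1", "roc_auc")
  print(as.data.frame(df), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @rdname ablation_study
#' @param x,object An `ablation_report`.
#' @param ... Unused.
#' @export
tidy.ablation_report <- function(x, ...) {
  dplyr::select(x$metrics, "feature_set", "classifier", "precision", "recall",
                "f1", "roc_auc")
}

#' @rdname ablation_study
#' @export
glance.ablation_report <- function(x, ...) {
  best <- x$metrics[which.max(x$metrics$f1), ]
  tibble::tibble(
    n_models = nrow(x$metrics), folds = x$folds, seed = x$seed,
    best_f1 = best$f1, best_f1_model = paste(best$classifier, "on", best$feature_set),
    best_auc = max(x$metrics$roc_auc)
  )
}

#' @rdname ablation_study
#' @export
autoplot.ablation_report <- function(object, ...) {
  curves <- object$metrics |>
    dplyr::mutate(model = paste(.data$classifier, .data$feature_set, sep = " / ")) |>
    dplyr::select("model", "feature_set", "classifier", "roc") |>
    tidyr::unnest("roc")
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       colour = .data$classifier)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~feature_set) +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = "Cross-validated ROC curves by feature set") +
    ggplot2::theme_minimal()
}
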