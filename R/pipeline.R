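#' End-to-end screening run
#'
#' Orchestrates the whole procedure in its methodological order: (optionally)
#' generate or load the inputs, score every phrase on the three channels,
#' produce the dissociation (chi-square) report, then run the ablation
#' classification study, writing every stage artifact plus a run manifest to
#' `out_dir`. The chi-square stage is advisory: its outcome is logged in the
#' report but never blocks classification.
#'
#' @param config Run configuration: either a [synth_config()] (synthetic
#'   inputs are generated) or a list with elements `phrases` (data frame or
#'   CSV path with columns `phrase_id`, `interview_id`, `class`, `text`,
#'   `emotion`), `corpus` (character vector or text-file path), and optional
#'   `tau`, `smoothing`, `alpha`, `folds`, `seed`.
#' @param out_dir Output directory, created if needed.
#' @param folds,alpha,tau,smoothing,seed Stage parameters; override any
#'   values carried by `config`.
#' @return Invisibly, a list with `scored` (tibble), `training` (tibble),
#'   `dissociation` (report object), `ablation` (`ablation_report` or NULL if
#'   only one class was present) and `manifest`.
#' @export
run_screening <- function(config = synth_config(), out_dir,
                          folds = 10, alpha = 0.05, tau = 0.5, smoothing = 0.5,
                          seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message(sprintf(...))

  if (inherits(config, "synth_config")) {
    seed <- seed %||% config$seed
    log_msg("stage generate: synthesizing %d+%d interviews x %d phrases (seed %d)",
            config$n_control_interviews, config$n_case_interviews,
            config$phrases_per_interview, config$seed)
    dataset <- generate_dataset(config)
    phrases <- dataset$phrases
    corpus <- dataset$corpus
    write_dataset(dataset, file.path(out_dir, "data"))
    config_snapshot <- unclass(config)
  } else {
    seed <- seed %||% config$seed %||% 1
    tau <- config$tau %||% tau
    smoothing <- config$smoothing %||% smoothing
    phrases <- config$phrases
    if (is.character(phrases) && length(phrases) == 1) {
      phrases <- readr::read_csv(phrases, col_types = readr::cols())
    }
    corpus <- config$corpus
    if (is.character(corpus) && length(corpus) == 1 && file.exists(corpus)) {
      corpus <- readLines(corpus, encoding = "UTF-8", warn = FALSE)
    }
    config_snapshot <- list(tau = tau, smoothing = smoothing, seed = seed)
  }
  phrases <- tibble::as_tibble(phrases)
  input_digest <- digest_rows(phrases)

  log_msg("stage score: %d phrases on 3 channels", nrow(phrases))
  stats <- count_corpus(corpus, smoothing = smoothing)
  scored <- phrases |>
    score_phrases() |>
    orient_phrases(stats, tau = tau) |>
    band_tone()
  readr::write_csv(scored, file.path(out_dir, "scored.csv"))

  training <- build_training_file(scored)
  write_training_file(training, file.path(out_dir, "training.csv"))

  n_classes <- dplyr::n_distinct(scored$class)
  log_msg("stage test: chi-square dissociation report (%d group%s)",
          n_classes, if (n_classes == 1) "" else "s")
  disso <- dissociation_report(training, alpha = alpha, require_two = FALSE)
  flagged <- disso$pairwise$p_value >= alpha
  if (any(flagged)) {
    log_msg("  advisory: %d group/channel pair(s) show dissociation (p >= %g)",
            sum(flagged), alpha)
  }
  jsonlite::write_json(report_as_list(disso), file.path(out_dir, "dissociation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ablation <- NULL
  if (n_classes == 2) {
    log_msg("stage classify: ablation study, %d-fold CV, seed %d", folds, seed)
    ablation <- ablation_study(training, folds = folds, seed = seed)
    jsonlite::write_json(
      list(config = ablation$config, folds = folds, seed = seed,
           metrics = tidy(ablation)),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    roc_csv <- ablation$metrics |>
      dplyr::select("feature_set", "classifier", "roc") |>
      tidyr::unnest("roc")
    readr::write_csv(roc_csv, file.path(out_dir, "roc_points.csv"))
  } else {
    log_msg("stage classify: refused (needs exactly 2 classes, got %d)", n_classes)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dissoscreen")),
    config = config_snapshot,
    seed = seed, folds = folds, alpha = alpha, tau = tau, smoothing = smoothing,
    input_digest = input_digest,
    rows = list(phrases = nrow(phrases), scored = nrow(scored),
                training = nrow(training))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(scored = scored, training = training, dissociation = disso,
                 ablation = ablation, manifest = manifest))
}

# Dependency-free content digest (djb2 over the serialized rows), recorded in
# the manifest before processing so reruns can detect changed inputs.
digest_rows <- function(df) {
  txt <- paste(capture_csv(df), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("djb2:%d:%d", nrow(df), h)
}

capture_csv <- function(df) {
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  out
}
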