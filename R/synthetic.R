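#' Configuration for the synthetic phrase-corpus generator
#'
#' Captures the study structure the generator emulates: a control cohort of 60
#' interviews and a case cohort of 22 interviews, 300 phrases each, with a
#' latent per-phrase valence that the three channels (polarity, semantic
#' orientation, tone) reproduce faithfully in controls and lose in cases.
#'
#' @param n_control_interviews,n_case_interviews Interview counts per group
#'   (defaults 60 and 22).
#' @param phrases_per_interview Phrases per interview (default 300).
#' @param valence_distribution Probabilities of a phrase's latent valence being
#'   positive / neutral / negative. The default leans positive with few fully
#'   neutral phrases, the pattern of reminiscence interviews.
#' @param concordance Probability that a channel reproduces the latent valence
#'   in the concordant regime; otherwise it takes a uniformly random other
#'   level.
#' @param dissociation Probability that a case phrase is decoupled: its three
#'   channels are drawn independently of the latent valence and of each other,
#'   uniformly over the three levels.
#' @param magnitude_distribution Probabilities over polarity magnitudes 1..5
#'   for non-neutral phrases. The default puts no mass on magnitude 1: under
#'   the dual-strength reduction rule a lone +/-1 sentiment hit ties with the
#'   scale's defaults and scores as the neutral +1, so an intended polarity of
#'   magnitude 1 is not recoverable from text and is reserved for neutral
#'   phrases.
#' @param seed Integer seed; the generated dataset is a pure function of the
#'   configuration including this seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_control_interviews = 60,
                         n_case_interviews = 22,
                         phrases_per_interview = 300,
                         valence_distribution = c(positive = 0.60, neutral = 0.10, negative = 0.30),
                         concordance = 0.95,
                         dissociation = 1.0,
                         magnitude_distribution = c(0, 0.38, 0.27, 0.20, 0.15),
                         seed = 1) {
  stopifnot(
    n_control_interviews >= 0, n_case_interviews >= 0, phrases_per_interview > 0,
    concordance >= 0, concordance <= 1, dissociation >= 0, dissociation <= 1
  )
  check_probs <- function(p, len, what) {
    if (length(p) != len || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(sprintf("%s must be %d nonnegative probabilities summing to 1", what, len),
           call. = FALSE)
    }
    p / sum(p)
  }
  valence_distribution <- check_probs(valence_distribution, 3, "valence_distribution")
  names(valence_distribution) <- c("positive", "neutral", "negative")
  magnitude_distribution <- check_probs(magnitude_distribution, 5, "magnitude_distribution")
  if (magnitude_distribution[1] > 0) {
    stop(paste("magnitude_distribution must put no mass on magnitude 1:",
               "a lone +/-1 hit ties with the scale defaults and scores neutral,",
               "so it cannot be recovered from text"), call. = FALSE)
  }
  structure(
    list(
      n_control_interviews = as.integer(n_control_interviews),
      n_case_interviews = as.integer(n_case_interviews),
      phrases_per_interview = as.integer(phrases_per_interview),
      valence_distribution = valence_distribution,
      concordance = concordance,
      dissociation = dissociation,
      magnitude_distribution = magnitude_distribution,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config: %d control + %d case interviews x %d phrases, concordance %.2f, dissociation %.2f, seed %d>\n",
    x$n_control_interviews, x$n_case_interviews, x$phrases_per_interview,
    x$concordance, x$dissociation, x$seed
  ))
  invisible(x)
}

# Vocabulary pools used by the text assembler. Fillers are deliberately absent
# from both the default lexicon and the reference corpus.
synth_fillers <- c("the", "a", "and", "then", "we", "i", "it", "was", "to",
                   "of", "on", "in", "that", "this", "my", "they")
synth_topics <- function() {
  list(
    excellent = sprintf("theme%03d", 1:40),
    neutral = sprintf("theme%03d", 81:120),
    poor = sprintf("theme%03d", 41:80)
  )
}

negative_emotions <- c("anger", "sadness", "boredom")

#' Generate a synthetic screening dataset
#'
#' Draws per-phrase channel triples under the concordant-control /
#' decoupled-case model of [synth_config()], then (optionally) assembles
#' phrase text from the packaged lexicon so that [score_phrase()] recovers the
#' intended polarity exactly, and a reference corpus whose co-occurrence
#' structure makes [semantic_orientation()] recover the intended orientation
#' code. Emotion labels are drawn uniformly among the names consistent with
#' the intended tone band.
#'
#' @param config A [synth_config()].
#' @param text Assemble phrase text and the reference corpus (default TRUE).
#'   With `text = FALSE` only the channel triples are generated — the fast
#'   path for large simulation studies on the statistics themselves.
#' @param lexicon Lexicon used for text assembly.
#' @return A list of class `synth_dataset` with elements `phrases` (tibble:
#'   `phrase_id`, `interview_id`, `class`, `text`, `emotion`), `truth`
#'   (tibble of intended per-phrase values: `polarity`, `polarity_label`,
#'   `so_code`, `tone_code`, latent valence and the dissociation flag),
#'   `corpus` (character vector of reference documents) and the `config`.
#' @export
generate_dataset <- function(config = synth_config(), text = TRUE,
                             lexicon = if (text) default_lexicon() else NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)

  n_ctrl <- config$n_control_interviews * config$phrases_per_interview
  n_case <- config$n_case_interviews * config$phrases_per_interview
  n <- n_ctrl + n_case
  if (n == 0) stop("configuration generates no phrases", call. = FALSE)

  cls <- rep(c("control", "case"), c(n_ctrl, n_case))
  interview_id <- c(
    if (n_ctrl) rep(sprintf("ctrl_%02d", seq_len(config$n_control_interviews)),
                    each = config$phrases_per_interview),
    if (n_case) rep(sprintf("case_%02d", seq_len(config$n_case_interviews)),
                    each = config$phrases_per_interview)
  )
  phrase_id <- sprintf("%s_p%03d", interview_id,
                       rep(seq_len(config$phrases_per_interview),
                           times = config$n_control_interviews + config$n_case_interviews))

  levels3 <- c(1L, 0L, -1L)  # positive, neutral, negative
  latent <- sample(levels3, n, replace = TRUE, prob = config$valence_distribution)
  dissociated <- cls == "case" & stats::runif(n) < config$dissociation

  draw_channel <- function() {
    out <- integer(n)
    u <- dissociated
    out[u] <- sample(levels3, sum(u), replace = TRUE)
    c_idx <- which(!u)
    keep <- stats::runif(length(c_idx)) < config$concordance
    out[c_idx[keep]] <- latent[c_idx[keep]]
    flip <- c_idx[!keep]
    if (length(flip) > 0) {
      # uniformly one of the two other levels
      shift <- sample(1:2, length(flip), replace = TRUE)
      cur <- match(latent[flip], levels3)
      out[flip] <- levels3[((cur - 1 + shift) %% 3) + 1]
    }
    out
  }
  pol_level <- draw_channel()
  so_code <- draw_channel()
  tone_code <- draw_channel()

  magnitude <- sample(1:5, n, replace = TRUE, prob = config$magnitude_distribution)
  polarity <- ifelse(pol_level == 0L, 1L, pol_level * magnitude)
  polarity_label <- c("negative", "neutral", "positive")[pol_level + 2L]

  emotion <- character(n)
  emotion[tone_code == 1L] <- "joy"
  emotion[tone_code == 0L] <- "neutral"
  neg_idx <- which(tone_code == -1L)
  emotion[neg_idx] <- sample(negative_emotions, length(neg_idx), replace = TRUE)

  truth <- tibble::tibble(
    phrase_id = phrase_id, class = cls,
    latent_valence = latent, dissociated = dissociated,
    polarity = as.integer(polarity), polarity_label = polarity_label,
    so_code = as.integer(so_code), tone_code = as.integer(tone_code)
  )

  phrase_text <- NULL
  corpus <- NULL
  if (text) {
    topics <- synth_topics()
    topic <- character(n)
    topic[so_code == 1L] <- sample(topics$excellent, sum(so_code == 1L), replace = TRUE)
    topic[so_code == 0L] <- sample(topics$neutral, sum(so_code == 0L), replace = TRUE)
    topic[so_code == -1L] <- sample(topics$poor, sum(so_code == -1L), replace = TRUE)
    phrase_text <- assemble_phrases(pol_level, magnitude, topic, lexicon)
    corpus <- reference_corpus()
  }

  phrases <- tibble::tibble(
    phrase_id = phrase_id, interview_id = interview_id, class = cls,
    text = phrase_text %||% NA_character_, emotion = emotion
  )

  structure(list(phrases = phrases, truth = truth, corpus = corpus,
                 config = config),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("<synth_dataset: %d phrases (%d control / %d case)%s>\n",
              nrow(x$phrases), sum(x$phrases$class == "control"),
              sum(x$phrases$class == "case"),
              if (is.null(x$corpus)) ", channels only" else
                sprintf(", corpus of %d documents", length(x$corpus))))
  invisible(x)
}

# Build phrase text whose dictionary score is exactly sign * magnitude
# (or neutral when the level is 0): a plain sentiment term, a boosted term,
# or a negated term of the opposite sign, padded with filler words and the
# phrase's topic word. The sentiment chain is kept contiguous so booster and
# negator scope survive tokenization.
assemble_phrases <- function(pol_level, magnitude, topic, lexicon) {
  by_strength <- split(names(lexicon$sentiment), lexicon$sentiment)
  missing_str <- setdiff(as.character(c(-5:-1, 1:5)), names(by_strength))
  if (length(missing_str) > 0) {
    stop(sprintf("text assembly needs sentiment terms at every strength; missing %s",
                 paste(missing_str, collapse = ", ")), call. = FALSE)
  }
  plus1 <- names(lexicon$booster)[lexicon$booster == 1L]
  negs <- lexicon$negators
  n <- length(pol_level)

  pick <- function(strength, k) {
    pool <- by_strength[[as.character(strength)]]
    pool[sample.int(length(pool), k, replace = TRUE)]
  }

  form <- integer(n)  # 0 neutral, 1 plain, 2 boosted, 3 negated
  nonneutral <- pol_level != 0L
  form[nonneutral] <- sample(1:3, sum(nonneutral), replace = TRUE,
                             prob = c(0.5, 0.25, 0.25))

  chain <- character(n)
  idx <- which(form == 1L)
  chain[idx] <- pick_by(idx, pol_level, magnitude, pick, 0L)
  idx <- which(form == 2L)
  if (length(idx) > 0) {
    chain[idx] <- paste(plus1[sample.int(length(plus1), length(idx), replace = TRUE)],
                        pick_by(idx, pol_level, magnitude, pick, -1L))
  }
  idx <- which(form == 3L)
  if (length(idx) > 0) {
    chain[idx] <- paste(negs[sample.int(length(negs), length(idx), replace = TRUE)],
                        pick_by(idx, -pol_level, magnitude, pick, 0L))
  }

  f <- function(k) synth_fillers[sample.int(length(synth_fillers), k, replace = TRUE)]
  lead <- f(n); mid <- f(n); tail_ <- f(n)
  out <- ifelse(nzchar(chain),
                paste(lead, chain, mid, topic, tail_),
                paste(lead, mid, topic, tail_))
  trimws(gsub(" +", " ", out))
}

pick_by <- function(idx, level, magnitude, pick, mag_shift) {
  strengths <- level[idx] * (magnitude[idx] + mag_shift)
  vapply(strengths, function(s) pick(s, 1L), character(1))
}

#' The synthetic reference corpus for SO-PMI
#'
#' One document per line pairing each topic word with its seed: "excellent"
#' topics co-occur only with "excellent", "poor" topics only with "poor", and
#' neutral topics equally with both. Under add-half smoothing this puts every
#' topic word about 3.2 bits from the opposite seed, well clear of the
#' default 0.5-bit trinary threshold.
#'
#' @return Character vector of documents.
#' @export
reference_corpus <- function() {
  topics <- synth_topics()
  c(
    rep(paste(topics$excellent, "excellent"), 4),
    rep(paste(topics$poor, "poor"), 4),
    rep(paste(topics$neutral, "excellent"), 2),
    rep(paste(topics$neutral, "poor"), 2)
  )
}

#' Training records straight from generator truth
#'
#' Convenience accessor: the intended channel values as a training table, for
#' simulation studies that bypass re-scoring the assembled text.
#'
#' @param dataset A `synth_dataset`.
#' @return Training tibble (see [build_training_file()]).
#' @export
as_training_records <- function(dataset) {
  stopifnot(inherits(dataset, "synth_dataset"))
  build_training_file(dataset$truth)
}

#' Verify the scorers recover the generator's intended channel values
#'
#' Runs the real polarity and semantic-orientation scorers on the generated
#' text and corpus and reports per-channel agreement with the generator's
#' intent. Polarity recovery is exact by construction; orientation recovery is
#' designed to exceed 95% at the default threshold.
#'
#' @param dataset A `synth_dataset` generated with `text = TRUE`.
#' @param lexicon Lexicon to score with (the one used for assembly).
#' @param tau Trinary threshold for [semantic_orientation()].
#' @return Tibble with one row per channel: `channel`, `agreement`, `n`.
#' @export
channel_recovery_check <- function(dataset, lexicon = default_lexicon(), tau = 0.5) {
  stopifnot(inherits(dataset, "synth_dataset"))
  if (nrow(dataset$phrases) == 0) stop("empty dataset", call. = FALSE)
  if (is.null(dataset$corpus)) stop("dataset was generated without text; rerun with text = TRUE", call. = FALSE)

  scored <- dataset$phrases |>
    score_phrases(lexicon = lexicon) |>
    orient_phrases(count_corpus(dataset$corpus), tau = tau) |>
    band_tone()

  joined <- dplyr::inner_join(
    dplyr::select(scored, "phrase_id", polarity_hat = "polarity",
                  label_hat = "polarity_label", so_hat = "so_code",
                  tone_hat = "tone_code"),
    dataset$truth, by = "phrase_id"
  )
  tibble::tibble(
    channel = c("polarity", "so_code", "tone_code"),
    agreement = c(
      mean(joined$polarity_hat == joined$polarity & joined$label_hat == joined$polarity_label),
      mean(joined$so_hat == joined$so_code),
      mean(joined$tone_hat == joined$tone_code)
    ),
    n = nrow(joined)
  )
}

#' Write a generated dataset to disk
#'
#' Emits `phrases.csv`, `truth.csv`, `corpus.txt` and `manifest.json`
#' (configuration and seed echo) under `dir`.
#'
#' @param dataset A `synth_dataset`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(dataset$phrases, file.path(dir, "phrases.csv"))
  readr::write_csv(dataset$truth, file.path(dir, "truth.csv"))
  if (!is.null(dataset$corpus)) {
    writeLines(dataset$corpus, file.path(dir, "corpus.txt"))
  }
  cfg <- unclass(dataset$config)
  jsonlite::write_json(
    list(config = cfg, n_phrases = nrow(dataset$phrases)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
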