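#' Load a sentiment lexicon from plain-text files
#'
#' Reads the three knowledge-base files of the dictionary polarity scorer:
#' sentiment terms with signed integer strengths, booster terms that shift the
#' strength of the following sentiment word, and negator terms that reverse its
#' sign. All files are UTF-8, one entry per line, tab-separated where a value is
#' carried (`term<TAB>strength` / `term<TAB>shift`); lines starting with `#` and
#' blank lines are ignored.
#'
#' @param sentiment_path Path to the sentiment-term file. Strengths are nonzero
#'   integers with absolute value at most 5: the sign is the valence, the
#'   magnitude the intensity.
#' @param booster_path Path to the booster file. Shifts must be -1, +1 or +2.
#' @param negator_path Path to the negator file, one term per line.
#' @return An object of class `lexicon`: a list with named integer vectors
#'   `sentiment` and `booster` and a character vector `negators`.
#' @details A term may appear in at most one of the three lists, and duplicates
#'   within a list are an error. Empty files are valid and yield an empty
#'   lexicon under which every phrase is neutral.
#' @seealso [default_lexicon()], [score_phrase()]
#' @examples
#' dir <- system.file("extdata", package = "dissoscreen")
#' lex <- load_lexicon(
#'   file.path(dir, "sentiment_terms_synthetic.tsv"),
#'   file.path(dir, "booster_terms.tsv"),
#'   file.path(dir, "negator_terms.txt")
#' )
#' sum(lex$sentiment > 0)
#' @export
load_lexicon <- function(sentiment_path, booster_path, negator_path) {
  sentiment <- read_term_value_file(sentiment_path, "sentiment")
  booster <- read_term_value_file(booster_path, "booster")
  negators <- read_term_file(negator_path)

  bad <- sentiment == 0L | abs(sentiment) > 5L
  if (any(bad)) {
    stop(sprintf(
      "invalid sentiment strength for term(s) %s in '%s': must be a nonzero integer in [-5, 5]",
      paste0("'", names(sentiment)[bad], "'", collapse = ", "), sentiment_path
    ), call. = FALSE)
  }
  bad <- !booster %in% c(-1L, 1L, 2L)
  if (any(bad)) {
    stop(sprintf(
      "invalid booster shift for term(s) %s in '%s': must be -1, +1 or +2",
      paste0("'", names(booster)[bad], "'", collapse = ", "), booster_path
    ), call. = FALSE)
  }

  all_terms <- c(names(sentiment), names(booster), negators)
  dup <- unique(all_terms[duplicated(all_terms)])
  if (length(dup) > 0) {
    stop(sprintf(
      "term(s) %s appear in more than one lexicon list",
      paste0("'", dup, "'", collapse = ", ")
    ), call. = FALSE)
  }

  structure(
    list(sentiment = sentiment, booster = booster, negators = negators),
    class = "lexicon"
  )
}

#' Build a lexicon from in-memory components
#'
#' Programmatic constructor used by tests and the synthetic-data generator;
#' applies the same validation as [load_lexicon()].
#'
#' @param sentiment Named integer vector of signed strengths.
#' @param booster Named integer vector of shifts in \{-1, +1, +2\}.
#' @param negators Character vector of negator terms.
#' @return A `lexicon` object.
#' @export
lexicon <- function(sentiment = integer(), booster = integer(), negators = character()) {
  sentiment <- validate_named_int(sentiment, "sentiment")
  booster <- validate_named_int(booster, "booster")
  negators <- as.character(negators)
  if (any(sentiment == 0L | abs(sentiment) > 5L)) {
    stop("sentiment strengths must be nonzero integers in [-5, 5]", call. = FALSE)
  }
  if (any(!booster %in% c(-1L, 1L, 2L))) {
    stop("booster shifts must be -1, +1 or +2", call. = FALSE)
  }
  all_terms <- c(names(sentiment), names(booster), negators)
  if (anyDuplicated(all_terms)) {
    stop("a term may appear in only one lexicon list", call. = FALSE)
  }
  structure(
    list(sentiment = sentiment, booster = booster, negators = negators),
    class = "lexicon"
  )
}

validate_named_int <- function(x, what) {
  if (length(x) == 0) return(stats::setNames(integer(), character()))
  if (is.null(names(x)) || any(names(x) == "")) {
    stop(sprintf("%s entries must be a named vector", what), call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    stop(sprintf("duplicate term in %s entries", what), call. = FALSE)
  }
  stats::setNames(as.integer(x), names(x))
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf(
    "<lexicon: %d positive / %d negative sentiment terms, %d boosters, %d negators>\n",
    sum(x$sentiment > 0), sum(x$sentiment < 0), length(x$booster), length(x$negators)
  ))
  invisible(x)
}

#' The packaged default lexicon
#'
#' Loads the synthetic default lexicon shipped with the package: 298
#' positive-strength and 465 negative-strength sentiment terms (the size of the
#' SentiStrength-style dictionary the scorer models), plus booster and negator
#' lists. The word list itself is synthetic -- generated pseudo-words around a
#' few real anchor words such as "happy" (+3) -- because no public word list at
#' these exact counts is bundled; only the counts and the scoring rules matter
#' to the pipeline.
#'
#' @return A `lexicon` object.
#' @export
default_lexicon <- function() {
  dir <- system.file("extdata", package = "dissoscreen")
  load_lexicon(
    file.path(dir, "sentiment_terms_synthetic.tsv"),
    file.path(dir, "booster_terms.tsv"),
    file.path(dir, "negator_terms.txt")
  )
}

read_term_value_file <- function(path, what) {
  lines <- read_lexicon_lines(path)
  if (length(lines$text) == 0) return(stats::setNames(integer(), character()))
  parts <- strsplit(lines$text, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  bad <- which(n_fields != 2)
  if (length(bad) > 0) {
    stop(sprintf(
      "malformed %s line %d in '%s': expected 'term<TAB>value', got '%s'",
      what, lines$lineno[bad[1]], path, lines$text[bad[1]]
    ), call. = FALSE)
  }
  terms <- vapply(parts, `[[`, character(1), 1)
  raw <- vapply(parts, `[[`, character(1), 2)
  vals <- suppressWarnings(as.integer(raw))
  bad <- which(is.na(vals) | vals != suppressWarnings(as.numeric(raw)))
  if (length(bad) > 0) {
    stop(sprintf(
      "malformed %s line %d in '%s': '%s' is not an integer",
      what, lines$lineno[bad[1]], path, raw[bad[1]]
    ), call. = FALSE)
  }
  dup <- unique(terms[duplicated(terms)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate term(s) %s in '%s'",
                 paste0("'", dup, "'", collapse = ", "), path), call. = FALSE)
  }
  stats::setNames(vals, terms)
}

read_term_file <- function(path) {
  lines <- read_lexicon_lines(path)
  terms <- lines$text
  bad <- grep("\t", terms, fixed = TRUE)
  if (length(bad) > 0) {
    stop(sprintf("malformed negator line %d in '%s': expected a bare term",
                 lines$lineno[bad[1]], path), call. = FALSE)
  }
  dup <- unique(terms[duplicated(terms)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate term(s) %s in '%s'",
                 paste0("'", dup, "'", collapse = ", "), path), call. = FALSE)
  }
  terms
}

read_lexicon_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  list(text = trimws(raw[keep], which = "right"), lineno = which(keep))
}

#' Tokenize a phrase
#'
#' Lowercases, splits on whitespace, and strips leading/trailing punctuation
#' from each token; empty tokens are dropped. No stemming is applied.
#'
#' @param text Character vector of phrases.
#' @return A list of character vectors, one per input phrase.
#' @export
tokenize <- function(text) {
  toks <- strsplit(tolower(text), "\\s+")
  lapply(toks, function(x) {
    x <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", x)
    x[nzchar(x)]
  })
}

#' Score one phrase with the dictionary polarity rules
#'
#' Applies the SentiStrength-style scoring rules to an ordered token sequence:
#' each sentiment token's effective magnitude is its base magnitude plus the
#' summed shifts of the booster tokens immediately preceding it (clamped to
#' \[1, 5\]; boosters never flip the sign), and a negator earlier in the same
#' booster chain reverses the final sign of the token together with its
#' boosters -- so with happy = +3 and very = +1, "very happy" scores +4 and
#' "not very happy" scores -4. Tokens not in the lexicon contribute nothing and
#' break a pending booster/negator chain.
#'
#' @param tokens Character vector of tokens (already tokenized; matching is
#'   case-insensitive) or a single untokenized string.
#' @param lexicon A [lexicon()] object.
#' @return A list of class `polarity_result` with integer fields
#'   `positive_strength` (in \[1, 5\]; the strongest positive hit, default 1),
#'   `negative_strength` (in \[-5, -1\]; the strongest negative hit, default -1),
#'   `scalar` (the dominant of the two by magnitude, positive on ties -- the
#'   single -5..5 value with no 0), and `label` ("positive", "negative", or
#'   "neutral" on a magnitude tie, including the no-hit case).
#' @examples
#' lex <- lexicon(sentiment = c(happy = 3L), booster = c(very = 1L), negators = "not")
#' score_phrase(c("very", "happy"), lex)$scalar      # 4
#' score_phrase(c("not", "very", "happy"), lex)$scalar  # -4
#' @export
score_phrase <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "lexicon"))
  if (length(tokens) == 1 && grepl("\\s", tokens)) tokens <- tokenize(tokens)[[1]]
  tokens <- tolower(as.character(tokens))

  hits <- integer(0)
  boost <- 0L
  negate <- FALSE
  in_chain <- FALSE
  for (tok in tokens) {
    if (tok %in% lexicon$negators) {
      negate <- if (in_chain) !negate else TRUE
      in_chain <- TRUE
    } else if (tok %in% names(lexicon$booster)) {
      boost <- (if (in_chain) boost else 0L) + lexicon$booster[[tok]]
      negate <- if (in_chain) negate else FALSE
      in_chain <- TRUE
    } else if (tok %in% names(lexicon$sentiment)) {
      base <- lexicon$sentiment[[tok]]
      mag <- abs(base) + (if (in_chain) boost else 0L)
      mag <- min(5L, max(1L, mag))
      eff <- sign(base) * mag
      if (in_chain && negate) eff <- -eff
      hits <- c(hits, eff)
      boost <- 0L; negate <- FALSE; in_chain <- FALSE
    } else {
      # unknown token breaks any pending booster/negator chain
      boost <- 0L; negate <- FALSE; in_chain <- FALSE
    }
  }

  pos <- if (any(hits > 0)) max(hits[hits > 0]) else 1L
  neg <- if (any(hits < 0)) min(hits[hits < 0]) else -1L
  scalar <- if (pos >= abs(neg)) pos else neg
  label <- if (pos > abs(neg)) "positive" else if (pos < abs(neg)) "negative" else "neutral"
  structure(
    list(positive_strength = as.integer(pos), negative_strength = as.integer(neg),
         scalar = as.integer(scalar), label = label),
    class = "polarity_result"
  )
}

#' @export
print.polarity_result <- function(x, ...) {
  cat(sprintf("<polarity: %+d (pos %d / neg %d, %s)>\n",
              x$scalar, x$positive_strength, x$negative_strength, x$label))
  invisible(x)
}

#' Score a phrase table on the polarity channel
#'
#' Data-frame-first wrapper around [score_phrase()]: tokenizes the `text`
#' column and appends the polarity columns.
#'
#' @param phrases A data frame with at least a `text` column; typically also
#'   `phrase_id`, `interview_id`, `class`, `emotion`.
#' @param lexicon A [lexicon()] object; defaults to the packaged lexicon.
#' @return The input as a tibble with added integer columns
#'   `positive_strength`, `negative_strength`, `polarity` (the scalar) and
#'   character column `polarity_label`.
#' @export
score_phrases <- function(phrases, lexicon = default_lexicon()) {
  stopifnot(is.data.frame(phrases), "text" %in% names(phrases))
  toks <- tokenize(phrases$text)
  res <- lapply(toks, score_phrase, lexicon = lexicon)
  dplyr::bind_cols(
    tibble::as_tibble(phrases),
    tibble::tibble(
      positive_strength = vapply(res, `[[`, integer(1), "positive_strength"),
      negative_strength = vapply(res, `[[`, integer(1), "negative_strength"),
      polarity = vapply(res, `[[`, integer(1), "scalar"),
      polarity_label = vapply(res, `[[`, character(1), "label")
    )
  )
}
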