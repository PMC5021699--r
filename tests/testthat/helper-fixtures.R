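# Shared fixtures: toy lexicons, literal-rule oracles, tiny corpora.

toy_lexicon <- function() {
  lexicon(
    sentiment = c(happy = 3L, good = 2L, terrible = -4L, sad = -2L),
    booster = c(very = 1L, slightly = -1L),
    negators = "not"
  )
}

# Literal, independent application of the scoring rules, used as the oracle
# for short phrases: for each sentiment token, walk back over the contiguous
# run of booster/negator tokens, sum the booster shifts, clamp the magnitude
# to [1, 5], and flip the sign once per negator; then reduce with the
# max/min/dominant-magnitude rule (ties are neutral with scalar +1).
oracle_score <- function(tokens, lex) {
  tokens <- tolower(tokens)
  is_boost <- tokens %in% names(lex$booster)
  is_neg <- tokens %in% lex$negators
  is_sent <- tokens %in% names(lex$sentiment)
  hits <- integer(0)
  for (i in which(is_sent)) {
    shift <- 0L; flips <- 0L
    j <- i - 1L
    while (j >= 1 && (is_boost[j] || is_neg[j])) {
      if (is_boost[j]) shift <- shift + lex$booster[[tokens[j]]]
      if (is_neg[j]) flips <- flips + 1L
      j <- j - 1L
    }
    base <- lex$sentiment[[tokens[i]]]
    eff <- sign(base) * min(5L, max(1L, abs(base) + shift)) * (-1L)^flips
    hits <- c(hits, eff)
  }
  pos <- if (any(hits > 0)) max(hits[hits > 0]) else 1L
  neg <- if (any(hits < 0)) min(hits[hits < 0]) else -1L
  list(
    positive_strength = pos, negative_strength = neg,
    scalar = if (pos >= abs(neg)) pos else neg,
    label = if (pos > abs(neg)) "positive" else if (pos < abs(neg)) "negative" else "neutral"
  )
}

# Corpus with exact count structure: n windows, c(a), c(b), c(ab).
counts_corpus <- function(n, ca, cb, cab, a = "alpha", b = "beta") {
  both <- rep(paste(a, b), cab)
  only_a <- rep(a, ca - cab)
  only_b <- rep(b, cb - cab)
  rest <- rep("pad", n - length(both) - length(only_a) - length(only_b))
  c(both, only_a, only_b, rest)
}

# Table 2-style bare records (class, polarity, so_code, tone_code).
records_tbl <- function(...) {
  m <- matrix(c(...), ncol = 4, byrow = TRUE)
  tibble::tibble(
    class = c("control", "case")[as.integer(m[, 1])],
    polarity = as.integer(m[, 2]),
    so_code = as.integer(m[, 3]),
    tone_code = as.integer(m[, 4])
  )
}

# The 12 case-group rows of the example training file.
alzheimer_rows <- function() {
  records_tbl(
    2, 5, -1, -1,
    2, -3, 1, 0,
    2, 5, 0, 1,
    2, 5, 1, 1,
    2, -1, 1, 1,
    2, -1, 0, 1,
    2, 3, 1, -1,
    2, 5, 0, 0,
    2, 3, 1, -1,
    2, -4, 1, 1,
    2, -5, 0, 1,
    2, 5, 1, -1
  )
}

small_config <- function(seed = 7, ...) {
  synth_config(n_control_interviews = 4, n_case_interviews = 3,
               phrases_per_interview = 50, seed = seed, ...)
}
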