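#' Count term and co-occurrence statistics over a reference corpus
#'
#' Builds the presence counts that the pointwise-mutual-information (PMI)
#' machinery needs. The co-occurrence window is one document (one line of the
#' corpus file): a term is counted at most once per document, and a pair is
#' counted in every document containing both terms.
#'
#' @param corpus Character vector of documents (one element per document), or a
#'   path to a UTF-8 text file with one document per line.
#' @param vocabulary Optional character vector restricting the counted terms.
#' @param smoothing Positive pseudo-count added to every count when
#'   probabilities are formed (add-half by default); keeps every PMI finite.
#' @return An object of class `corpus_stats` with fields `n_windows`,
#'   `term_counts` (named integer vector), `postings` (term -> sorted document
#'   indices, from which pair counts are derived), and `smoothing`.
#' @examples
#' stats <- count_corpus(c("good excellent", "bad poor"))
#' stats$term_counts[["excellent"]]
#' @export
count_corpus <- function(corpus, vocabulary = NULL, smoothing = 0.5) {
  if (length(corpus) == 1 && !grepl("\\s", corpus) && file.exists(corpus)) {
    corpus <- readLines(corpus, encoding = "UTF-8", warn = FALSE)
  }
  corpus <- as.character(corpus)
  corpus <- corpus[nzchar(trimws(corpus))]
  if (length(corpus) == 0) stop("corpus must contain at least one non-empty document", call. = FALSE)
  if (!is.numeric(smoothing) || length(smoothing) != 1 || smoothing <= 0) {
    stop("smoothing must be a single positive number", call. = FALSE)
  }

  doc_terms <- lapply(tokenize(corpus), unique)
  if (!is.null(vocabulary)) {
    vocabulary <- tolower(as.character(vocabulary))
    doc_terms <- lapply(doc_terms, function(x) x[x %in% vocabulary])
  }

  flat <- unlist(doc_terms, use.names = FALSE)
  doc_idx <- rep.int(seq_along(doc_terms), lengths(doc_terms))
  postings <- split(doc_idx, flat)
  term_counts <- vapply(postings, length, integer(1))

  structure(
    list(
      n_windows = length(doc_terms),
      term_counts = term_counts,
      postings = postings,
      smoothing = smoothing
    ),
    class = "corpus_stats"
  )
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf("<corpus_stats: %d windows, %d terms, smoothing %g>\n",
              x$n_windows, length(x$term_counts), x$smoothing))
  invisible(x)
}

term_count <- function(stats, term) {
  n <- unname(stats$term_counts[term])
  if (is.na(n)) 0L else n
}

#' Co-occurrence count of two terms
#'
#' Number of corpus windows containing both terms; symmetric, and never larger
#' than either term's own window count.
#'
#' @param stats A [count_corpus()] result.
#' @param term1,term2 Single terms.
#' @return Integer count.
#' @export
pair_count <- function(stats, term1, term2) {
  p1 <- stats$postings[[term1]]
  p2 <- stats$postings[[term2]]
  if (is.null(p1) || is.null(p2)) return(0L)
  length(intersect(p1, p2))
}

#' Pointwise mutual information of two terms, in bits
#'
#' Computes `log2(P(t1 & t2) / (P(t1) P(t2)))` with smoothed probability
#' estimates `P = (count + s) / (n_windows + 2 s)` so the value is finite even
#' for unseen terms or pairs. Positive values mean the terms co-occur more than
#' independence predicts; 0 means independence; negative means avoidance.
#'
#' @param term1,term2 Single terms (lowercased internally).
#' @param stats A [count_corpus()] result.
#' @return A single numeric value in bits. Symmetric in its two terms.
#' @export
pmi <- function(term1, term2, stats) {
  stopifnot(inherits(stats, "corpus_stats"))
  term1 <- tolower(term1); term2 <- tolower(term2)
  s <- stats$smoothing
  denom <- stats$n_windows + 2 * s
  p1 <- (term_count(stats, term1) + s) / denom
  p2 <- (term_count(stats, term2) + s) / denom
  p12 <- (pair_count(stats, term1, term2) + s) / denom
  log2(p12 / (p1 * p2))
}

#' Semantic orientation of a token sequence
#'
#' SO-PMI against the fixed seed pair: the phrase's association with
#' "excellent" minus its association with "poor",
#' `SO = PMI(phrase, "excellent") - PMI(phrase, "poor")`, where the
#' phrase-level PMI is the mean of token-level PMI over the phrase's content
#' tokens (those present in the corpus vocabulary). The sign of SO, thresholded
#' at `tau`, gives the trinary orientation code: +1 "excellent", 0 neutral,
#' -1 "poor".
#'
#' @param tokens Character vector of tokens, or a single untokenized string.
#' @param stats A [count_corpus()] result over the reference corpus.
#' @param tau Nonnegative threshold in bits for the trinary code (default 0.5):
#'   `so_code = +1` if `so >= tau`, `-1` if `so <= -tau`, else 0.
#' @return A list of class `so_result` with fields `pmi_excellent`, `pmi_poor`,
#'   `so` (all in bits), `so_code`, and `oov` (TRUE when the phrase had no
#'   content token, in which case `so = 0` and the code is neutral).
#' @export
semantic_orientation <- function(tokens, stats, tau = 0.5) {
  stopifnot(inherits(stats, "corpus_stats"), tau >= 0)
  if (length(tokens) == 1 && grepl("\\s", tokens)) tokens <- tokenize(tokens)[[1]]
  tokens <- tolower(as.character(tokens))
  content <- unique(tokens[tokens %in% names(stats$term_counts)])

  if (length(content) == 0) {
    res <- list(pmi_excellent = NA_real_, pmi_poor = NA_real_, so = 0,
                so_code = 0L, oov = TRUE)
    return(structure(res, class = "so_result"))
  }
  pe <- mean(vapply(content, pmi, numeric(1), term2 = "excellent", stats = stats))
  pp <- mean(vapply(content, pmi, numeric(1), term2 = "poor", stats = stats))
  so <- pe - pp
  code <- if (so >= tau) 1L else if (so <= -tau) -1L else 0L
  structure(
    list(pmi_excellent = pe, pmi_poor = pp, so = so, so_code = code, oov = FALSE),
    class = "so_result"
  )
}

#' @export
print.so_result <- function(x, ...) {
  cat(sprintf("<so: %+.3f bits (code %+d%s)>\n", x$so, x$so_code,
              if (x$oov) ", out-of-vocabulary" else ""))
  invisible(x)
}

#' Score a phrase table on the semantic-orientation channel
#'
#' Data-frame-first wrapper around [semantic_orientation()].
#'
#' @param phrases A data frame with a `text` column.
#' @param stats A [count_corpus()] result.
#' @param tau Trinary threshold in bits, see [semantic_orientation()].
#' @return The input as a tibble with added columns `pmi_excellent`,
#'   `pmi_poor`, `so`, `so_code` and logical `so_oov`.
#' @export
orient_phrases <- function(phrases, stats, tau = 0.5) {
  stopifnot(is.data.frame(phrases), "text" %in% names(phrases))
  res <- lapply(tokenize(phrases$text), semantic_orientation, stats = stats, tau = tau)
  dplyr::bind_cols(
    tibble::as_tibble(phrases),
    tibble::tibble(
      pmi_excellent = vapply(res, `[[`, numeric(1), "pmi_excellent"),
      pmi_poor = vapply(res, `[[`, numeric(1), "pmi_poor"),
      so = vapply(res, `[[`, numeric(1), "so"),
      so_code = vapply(res, `[[`, integer(1), "so_code"),
      so_oov = vapply(res, `[[`, logical(1), "oov")
    )
  )
}
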