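#' Chi-square association between two channels within one group
#'
#' Builds the observed contingency table between two of the three channels and
#' runs a Pearson chi-square test of independence (no continuity correction).
#' A small p-value is evidence the channels move together (association, the
#' pattern expected of cognitively healthy speakers); a large one is evidence
#' of dissociation.
#'
#' By default the text-derived channel (`polarity_sign` or `so_code`) is
#' collapsed to its sign with neutral phrases dropped, so a text-by-tone table
#' is 2 x 3 with 2 degrees of freedom; set `binarize = FALSE` for full
#' trinary-by-trinary (df 4) tables.
#'
#' @param records Data frame of per-phrase records with columns `polarity`,
#'   `so_code`, `tone_code`, optionally `polarity_label` and `class`.
#' @param group Optional single class label; rows are filtered to it first
#'   (requires a `class` column).
#' @param channel_a,channel_b One of `"polarity_sign"`, `"so_code"`,
#'   `"tone_code"`.
#' @param binarize Collapse `channel_a` (when it is a text channel) to binary
#'   sign, dropping neutrals.
#' @return Object of class `contingency_result`: observed `table`, `statistic`,
#'   `df`, `p_value`, logical `expected_ok` (FALSE if any expected cell < 5),
#'   `n` phrases used, and the channel/group annotation.
#' @examples
#' recs <- tibble::tibble(
#'   polarity = c(3, -2, 4, -5, 1, -1), so_code = c(1, -1, 1, -1, 0, 0),
#'   tone_code = c(1, -1, 1, -1, 0, -1)
#' )
#' channel_association(recs, channel_a = "so_code", channel_b = "tone_code",
#'                     binarize = FALSE)
#' @export
channel_association <- function(records, group = NULL,
                                channel_a = "polarity_sign",
                                channel_b = "tone_code",
                                binarize = TRUE) {
  records <- tibble::as_tibble(records)
  if (!is.null(group)) {
    if (!"class" %in% names(records)) stop("records need a 'class' column to filter by group", call. = FALSE)
    records <- dplyr::filter(records, .data$class == group)
  }
  if (nrow(records) == 0) stop(sprintf("no records in group '%s'", group %||% "<all>"), call. = FALSE)

  a <- channel_values(records, channel_a)
  b <- channel_values(records, channel_b)
  if (binarize && channel_a %in% c("polarity_sign", "so_code")) {
    keep <- a != 0 & !is.na(a)
    a <- a[keep]; b <- b[keep]
  }
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]

  if (length(unique(a)) < 2 || length(unique(b)) < 2) {
    stop(sprintf(
      "degenerate table: channel '%s' in group '%s' has fewer than 2 observed levels",
      if (length(unique(a)) < 2) channel_a else channel_b, group %||% "<all>"
    ), call. = FALSE)
  }

  tbl <- table(a, b, dnn = c(channel_a, channel_b))
  ht <- suppressWarnings(stats::chisq.test(tbl, correct = FALSE))
  structure(
    list(
      table = tbl,
      statistic = unname(ht$statistic),
      df = unname(ht$parameter),
      p_value = unname(ht$p.value),
      expected_ok = all(ht$expected >= 5),
      n = sum(tbl),
      group = group %||% NA_character_,
      channel_a = channel_a,
      channel_b = channel_b
    ),
    class = "contingency_result"
  )
}

channel_values <- function(records, channel) {
  switch(channel,
    polarity_sign = {
      if (!"polarity" %in% names(records)) stop("records need a 'polarity' column", call. = FALSE)
      s <- sign(records$polarity)
      if ("polarity_label" %in% names(records)) s[records$polarity_label == "neutral"] <- 0L
      as.integer(s)
    },
    so_code = as.integer(records[["so_code"]] %||% stop("records need a 'so_code' column", call. = FALSE)),
    tone_code = as.integer(records[["tone_code"]] %||% stop("records need a 'tone_code' column", call. = FALSE)),
    stop(sprintf("unknown channel '%s'", channel), call. = FALSE)
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Chi-square independence test: %s x %s%s\n", x$channel_a, x$channel_b,
              if (!is.na(x$group)) sprintf(" (group %s)", x$group) else ""))
  print(x$table)
  cat(sprintf("X-squared = %.4g, df = %d, p = %.4g%s\n", x$statistic, x$df, x$p_value,
              if (!x$expected_ok) "  [warning: expected cell count < 5]" else ""))
  invisible(x)
}

#' @rdname channel_association
#' @param x A `contingency_result`.
#' @param ... Unused.
#' @export
tidy.contingency_result <- function(x, ...) {
  tibble::tibble(
    group = x$group, channel_a = x$channel_a, channel_b = x$channel_b,
    statistic = x$statistic, df = x$df, p_value = x$p_value,
    n = x$n, expected_ok = x$expected_ok
  )
}

#' Per-phrase cross-channel concordance rate
#'
#' Fraction of phrases whose three channels agree: the polarity sign, the
#' semantic-orientation code and the tone band are all equal and nonzero, or
#' all neutral. When a `polarity_label` column is present, a "neutral" label
#' counts as the polarity channel's neutral level (the -5..5 scale itself has
#' no 0); otherwise the sign of `polarity` is used as-is.
#'
#' @param records Data frame with `polarity`, `so_code`, `tone_code` and
#'   optionally `polarity_label`.
#' @return A single number in \[0, 1\].
#' @export
concordance_rate <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) stop("records must be non-empty", call. = FALSE)
  p <- channel_values(records, "polarity_sign")
  s <- channel_values(records, "so_code")
  t <- channel_values(records, "tone_code")
  mean(p == s & s == t)
}

#' Group-wise dissociation report
#'
#' The core screening summary: for every diagnostic group, Pearson chi-square
#' association tests for the two text-versus-tone channel pairs
#' (polarity-tone and SO-tone) plus the per-phrase concordance rate; and,
#' separately, each channel's association with the class label across groups.
#' Healthy-like groups show strong within-group association (small p);
#' dissociated groups do not.
#'
#' @param records Data frame with `class`, `polarity`, `so_code`, `tone_code`
#'   and optionally `polarity_label`; at least two groups.
#' @param alpha Advisory significance level echoed into the report.
#' @param binarize Passed to [channel_association()].
#' @param require_two Error when fewer than two groups are present (default).
#'   With `FALSE`, a single-group input yields a reduced report (per-group
#'   tests and concordance only; no channel-vs-class tests).
#' @return Object of class `dissociation_report` with tibbles `pairwise`
#'   (one row per group x channel pair), `concordance` (one row per group) and
#'   `class_association` (one row per channel).
#' @export
dissociation_report <- function(records, alpha = 0.05, binarize = TRUE,
                                require_two = TRUE) {
  records <- tibble::as_tibble(records)
  if (!"class" %in% names(records)) stop("records need a 'class' column", call. = FALSE)
  groups <- sort(unique(as.character(records$class)))
  if (length(groups) < 2 && require_two) {
    stop("dissociation report needs at least 2 groups", call. = FALSE)
  }

  pairs <- list(c("polarity_sign", "tone_code"), c("so_code", "tone_code"))
  pairwise <- purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(pairs, function(pr) {
      tidy(channel_association(records, group = g, channel_a = pr[1],
                               channel_b = pr[2], binarize = binarize))
    })
  })

  concordance <- records |>
    dplyr::group_by(group = as.character(.data$class)) |>
    dplyr::summarise(concordance = concordance_rate(dplyr::pick(dplyr::everything())),
                     n = dplyr::n(), .groups = "drop")

  class_association <- if (length(groups) < 2) {
    tibble::tibble(channel = character(), statistic = numeric(),
                   df = integer(), p_value = numeric())
  } else {
    purrr::map_dfr(
      c("polarity_sign", "so_code", "tone_code"),
      function(ch) {
        v <- channel_values(records, ch)
        tbl <- table(v, as.character(records$class))
        ht <- suppressWarnings(stats::chisq.test(tbl, correct = FALSE))
        tibble::tibble(channel = ch, statistic = unname(ht$statistic),
                       df = unname(ht$parameter), p_value = unname(ht$p.value))
      }
    )
  }

  structure(
    list(pairwise = pairwise, concordance = concordance,
         class_association = class_association, alpha = alpha,
         binarize = binarize),
    class = "dissociation_report"
  )
}

#' @export
print.dissociation_report <- function(x, ...) {
  cat("Dissociation report (Pearson chi-square p-values by group)\n\n")
  wide <- x$pairwise |>
    dplyr::mutate(pair = paste0(.data$channel_a, " x ", .data$channel_b)) |>
    dplyr::select("group", "pair", "p_value") |>
    tidyr::pivot_wider(names_from = "pair", values_from = "p_value")
  wide <- dplyr::left_join(wide, x$concordance, by = "group")
  print(as.data.frame(wide), digits = 3, row.names = FALSE)
  cat(sprintf("\nAssociation with p < %g indicates concordant channels (healthy-like pattern).\n",
              x$alpha))
  cat("\nChannel vs class label:\n")
  print(as.data.frame(x$class_association), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @rdname dissociation_report
#' @param x A `dissociation_report`.
#' @param ... Unused.
#' @export
tidy.dissociation_report <- function(x, ...) {
  x$pairwise
}

#' @rdname dissociation_report
#' @export
glance.dissociation_report <- function(x, ...) {
  tibble::tibble(
    n_groups = dplyr::n_distinct(x$pairwise$group),
    n_tests = nrow(x$pairwise),
    n_associated = sum(x$pairwise$p_value < x$alpha),
    min_p = min(x$pairwise$p_value),
    max_p = max(x$pairwise$p_value),
    alpha = x$alpha
  )
}

#' @rdname dissociation_report
#' @param object A `dissociation_report`.
#' @export
autoplot.dissociation_report <- function(object, ...) {
  dat <- object$pairwise |>
    dplyr::mutate(pair = paste0(.data$channel_a, " × ", .data$channel_b),
                  neglog_p = -log10(pmax(.data$p_value, 1e-300)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pair, y = .data$neglog_p,
                                    fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(-log[10]~p),
                  title = "Channel association by group",
                  subtitle = "dashed line: advisory significance level") +
    ggplot2::theme_minimal()
}

report_as_list <- function(x) {
  list(
    alpha = x$alpha,
    binarize = x$binarize,
    pairwise = x$pairwise,
    concordance = x$concordance,
    class_association = x$class_association
  )
}
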