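test_that("binarized-text by trinary-tone tables have 2 degrees of freedom", {
  set.seed(3)
  recs <- tibble::tibble(
    polarity = sample(c(-4:-1, 1:4), 400, replace = TRUE),
    so_code = sample(-1:1, 400, replace = TRUE),
    tone_code = sample(-1:1, 400, replace = TRUE)
  )
  a <- channel_association(recs, channel_a = "polarity_sign", channel_b = "tone_code")
  expect_identical(a$df, 2L)
  expect_identical(dim(a$table), c(2L, 3L))
  b <- channel_association(recs, channel_a = "so_code", channel_b = "tone_code")
  expect_identical(b$df, 2L)
  # full trinary x trinary when binarization is off
  c_ <- channel_association(recs, channel_a = "so_code", channel_b = "tone_code",
                            binarize = FALSE)
  expect_identical(c_$df, 4L)
  # df invariant (rows-1)(cols-1) on every emitted table
  for (r in list(a, b, c_)) {
    expect_identical(r$df, as.integer(prod(dim(r$table) - 1)))
  }
})

test_that("proportional rows give statistic 0 and p = 1", {
  recs <- tibble::tibble(
    polarity = rep(c(2, -2), each = 30),
    so_code = rep(0L, 60),
    tone_code = rep(rep(-1:1, each = 10), 2)
  )
  r <- channel_association(recs, channel_a = "polarity_sign", channel_b = "tone_code")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("a hand-computed 2x2 table reproduces the unyated Pearson statistic", {
  # [[30,10],[10,30]]: all margins 40, expected 20 per cell, X^2 = 4*100/20 = 20
  recs <- tibble::tibble(
    polarity = rep(c(3, 3, -3, -3), c(30, 10, 10, 30)),
    so_code = rep(c(1, -1, 1, -1), c(30, 10, 10, 30)),
    tone_code = rep(c(1, -1, 1, -1), c(30, 10, 10, 30))
  )
  r <- channel_association(recs, channel_a = "polarity_sign", channel_b = "so_code")
  expect_equal(r$statistic, 20, tolerance = 1e-12)
  expect_identical(r$df, 1L)
  expect_equal(r$p_value, 7.744216e-06, tolerance = 1e-4)
})

test_that("the chi-square statistic is invariant to swapping the channels", {
  set.seed(11)
  recs <- tibble::tibble(
    polarity = sample(c(-3, -2, 2, 3), 200, replace = TRUE),
    so_code = sample(-1:1, 200, replace = TRUE),
    tone_code = sample(-1:1, 200, replace = TRUE)
  )
  ab <- channel_association(recs, channel_a = "so_code", channel_b = "tone_code",
                            binarize = FALSE)
  ba <- channel_association(recs, channel_a = "tone_code", channel_b = "so_code",
                            binarize = FALSE)
  expect_equal(ab$statistic, ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
  expect_identical(ab$table, t(ba$table))
})

test_that("degenerate and empty groups are rejected", {
  one_level <- tibble::tibble(polarity = rep(3, 20), so_code = rep(1L, 20),
                              tone_code = rep(-1:0, 10), class = "case")
  expect_error(channel_association(one_level, channel_a = "polarity_sign",
                                   channel_b = "tone_code"),
               "fewer than 2 observed levels")
  expect_error(channel_association(one_level, group = "control",
                                   channel_a = "polarity_sign",
                                   channel_b = "tone_code"),
               "no records")
})

test_that("concordance counts triples that agree in sign or are all neutral", {
  first_row <- records_tbl(1, 3, 1, 1)
  expect_equal(concordance_rate(first_row[rep(1, 5), ]), 1)
  expect_equal(concordance_rate(records_tbl(2, -5, -1, -1)), 1)
  # oracle-derived count over the printed case-group rows: one concordant triple
  expect_equal(concordance_rate(alzheimer_rows()), 1 / 12)
  # a neutral polarity label counts as the polarity channel's neutral level
  with_label <- tibble::tibble(polarity = 1L, polarity_label = "neutral",
                               so_code = 0L, tone_code = 0L)
  expect_equal(concordance_rate(with_label), 1)
  expect_error(concordance_rate(records_tbl(1, 3, 1, 1)[0, ]), "non-empty")
})

test_that("the report separates a concordant from a decoupled group", {
  ds <- generate_dataset(synth_config(n_control_interviews = 10,
                                      n_case_interviews = 10,
                                      phrases_per_interview = 100,
                                      seed = 13), text = FALSE)
  rep <- dissociation_report(as_training_records(ds))
  ctrl <- rep$pairwise[rep$pairwise$group == "control", ]
  expect_true(all(ctrl$p_value < 1e-6))
  expect_identical(unique(rep$pairwise$df), 2L)
  expect_gt(rep$concordance$concordance[rep$concordance$group == "control"],
            rep$concordance$concordance[rep$concordance$group == "case"])
  # broom-style accessors
  expect_identical(nrow(tidy(rep)), 4L)
  g <- glance(rep)
  expect_identical(g$n_groups, 2L)
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("identical groups give identical report rows", {
  set.seed(21)
  base <- tibble::tibble(
    polarity = sample(c(-3, 2, 4), 120, replace = TRUE),
    so_code = sample(-1:1, 120, replace = TRUE),
    tone_code = sample(-1:1, 120, replace = TRUE)
  )
  recs <- dplyr::bind_rows(
    dplyr::mutate(base, class = "control"),
    dplyr::mutate(base, class = "case")
  )
  rep <- dissociation_report(recs)
  a <- rep$pairwise[rep$pairwise$group == "case", -1]
  b <- rep$pairwise[rep$pairwise$group == "control", -1]
  expect_identical(a, b)
  expect_error(dissociation_report(dplyr::mutate(base, class = "x")),
               "at least 2 groups")
})

test_that("under exact independence the test rejects at close to its level", {
  n_rep <- 200
  p <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    set.seed(5000 + i)
    recs <- tibble::tibble(
      polarity = sample(c(-3, -2, 2, 3), 600, replace = TRUE),
      so_code = sample(-1:1, 600, replace = TRUE),
      tone_code = sample(-1:1, 600, replace = TRUE)
    )
    p[i] <- channel_association(recs, channel_a = "polarity_sign",
                                channel_b = "tone_code")$p_value
  }
  rate <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 3 * se + 1e-9)
})
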