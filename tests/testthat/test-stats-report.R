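test_that("Welch t statistic, df and p match independent formulas", {
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8)
  w <- welch_t_test(a, b)
  # independent implementation of the two formulas
  se2 <- var(a) / 4 + var(b) / 4
  t_ref <- (mean(a) - mean(b)) / sqrt(se2)
  df_ref <- se2^2 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  expect_equal(w$t_stat, t_ref)
  expect_equal(w$df_welch, df_ref)
  expect_equal(w$p_two_tailed, 2 * pt(-abs(t_ref), df_ref))
  # and the reference library implementation agrees
  tt <- stats::t.test(a, b)
  expect_equal(w$t_stat, unname(tt$statistic))
  expect_equal(w$df_welch, unname(tt$parameter))
  expect_equal(w$p_two_tailed, tt$p.value)
  expect_lte(w$df_welch, 4 + 4 - 2)
})

test_that("identical samples give t = 0, p = 1", {
  x <- c(1, 2, 3)
  w <- welch_t_test(x, x)
  expect_equal(w$t_stat, 0)
  expect_equal(w$p_two_tailed, 1)
})

test_that("equal-variance equal-n samples reduce to the pooled t exactly", {
  set.seed(10)
  for (i in 1:5) {
    a <- rnorm(12); b <- rnorm(12)
    w <- welch_t_test(a, b)
    sp2 <- (var(a) + var(b)) / 2
    t_pooled <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 12))
    expect_equal(w$t_stat, t_pooled)
  }
})

test_that("degenerate zero-variance cases are reported as specified", {
  w <- welch_t_test(c(1, 1, 1), c(1, 1, 1))
  expect_true(is.na(w$t_stat))
  w2 <- welch_t_test(c(2, 2, 2), c(1, 1, 1))
  expect_identical(w2$t_stat, Inf)
})

test_that("responding proportions reproduce printed count arithmetic", {
  expect_equal(proportion_responding(53, 730), 7.3)
  expect_equal(proportion_responding(26, 428), 6.1)
  expect_equal(proportion_responding(8, 675), 1.2)
  expect_equal(proportion_responding(1, 144), 0.7)
  expect_equal(proportion_responding(0, 100), 0)
  expect_error(proportion_responding(1, 0), "> 0")
  expect_error(proportion_responding(5, 4), "n_total")
})

test_that("complementary proportions sum to 100 pre-rounding", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(3:997, 1)
    a <- sample(0:n, 1)
    expect_equal(proportion_responding(a, n, digits = NULL) +
                   proportion_responding(n - a, n, digits = NULL), 100)
  }
})

make_summary <- function(label, n_vdrn, n_total, pct_change, onsets) {
  structure(list(condition_label = label, n_total_cells = n_total,
                 n_vdrn = n_vdrn,
                 responding_percent = proportion_responding(n_vdrn, n_total),
                 responding_percent_neg = NA_real_, excluded_cells = 0L,
                 exclusion_reasons = c(out_of_focus = 0L,
                                       electrically_unresponsive = 0L),
                 undefined_percent = FALSE, session_qc_pass = TRUE,
                 responder_percent_change = pct_change,
                 responder_onset_s = onsets),
            class = "slice_summary")
}

test_that("report: single condition yields one row; comparisons are consistent", {
  s1 <- make_summary("a", 2, 40, c(20, 30), c(200, 300))
  rep1 <- build_report(list(s1))
  expect_identical(nrow(rep1$condition_table), 1L)

  s2 <- make_summary("b", 3, 50, c(25, 35, 45), c(250, 350, 450))
  s1b <- make_summary("a", 1, 45, c(22, 28), c(180, 240))
  rep2 <- build_report(list(s1, s2, s1b))
  row <- rep2$comparison_table[
    rep2$comparison_table$measure == "cell_percent_change", ]
  w <- welch_t_test(c(20, 30, 22, 28), c(25, 35, 45))
  expect_equal(row$t_stat, w$t_stat)
  expect_equal(row$p_two_tailed, w$p_two_tailed)
})

test_that("report writing is deterministic", {
  s1 <- make_summary("a", 2, 40, c(20, 30), c(200, 300))
  s2 <- make_summary("b", 3, 50, c(25, 35, 45), c(250, 350, 450))
  d1 <- tempfile("rep1_"); d2 <- tempfile("rep2_")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  build_report(list(s1, s2), out_dir = d1)
  build_report(list(s2, s1), out_dir = d2)  # input order must not matter
  for (f in c("condition_summary.csv", "comparisons.csv", "report.txt")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
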