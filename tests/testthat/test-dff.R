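make_trace <- function(f1, f2, dt = 20) {
  structure(list(f1_series = f1, f2_series = f2,
                 cycle_times_s = seq_along(f1) * dt),
            class = "roi_trace")
}

test_that("instantaneous delta-F/F follows its defining formula", {
  tr <- make_trace(c(100, 100), c(100, 150))
  d <- instantaneous_dff(tr, drug_time_s = 60)
  expect_equal(d$values, c(0, 0.5))

  # element-by-element loop oracle on random positive paired series
  set.seed(42)
  for (rep in 1:5) {
    f1 <- runif(50, 50, 200)
    f2 <- runif(50, 50, 250)
    d <- instantaneous_dff(make_trace(f1, f2), drug_time_s = 1200)
    oracle <- numeric(50)
    for (i in 1:50) oracle[i] <- (f2[i] - f1[i]) / f1[i]
    expect_identical(d$values, oracle)
  }
})

test_that("delta-F/F properties: zero identity and ratio invariance", {
  set.seed(1)
  f1 <- runif(40, 50, 150)
  d0 <- instantaneous_dff(make_trace(f1, f1), drug_time_s = 900)
  expect_true(all(d0$values == 0))
  f2 <- f1 * runif(40, 0.9, 1.5)
  base <- instantaneous_dff(make_trace(f1, f2), drug_time_s = 900)$values
  for (c_ in c(0.5, 3, 117)) {
    scaled <- instantaneous_dff(make_trace(c_ * f1, c_ * f2),
                                drug_time_s = 900)$values
    expect_equal(scaled, base)
  }
})

test_that("nonpositive F1 cycles are flagged invalid and excluded", {
  tr <- make_trace(c(100, 0, 100, -5), c(110, 50, 120, 10))
  d <- instantaneous_dff(tr, drug_time_s = 100)
  expect_identical(d$valid, c(TRUE, FALSE, TRUE, FALSE))
  expect_true(all(is.na(d$values[!d$valid])))
})

test_that("baseline fitting selects flat or sloping correctly", {
  t_s <- seq(20, 600, by = 20)
  const <- structure(list(values = rep(0.2, length(t_s)), cycle_times_s = t_s,
                          drug_time_s = 600, baseline_window_s = c(0, 600),
                          valid = rep(TRUE, length(t_s))), class = "dff_series")
  bl <- fit_baseline(const)
  expect_identical(bl$kind, "flat")
  expect_equal(bl$intercept, 0.2)
  expect_equal(bl$slope, 0)
  expect_equal(bl$baseline_sd, 0)

  # noiseless sloping series: slope recovered to 1e-9
  slope_true <- -1e-4
  lin <- const
  lin$values <- 0.3 + slope_true * t_s
  bl2 <- fit_baseline(lin)
  expect_identical(bl2$kind, "sloping")
  expect_lt(abs(bl2$slope - slope_true), 1e-9)
  expect_lt(max(abs(predict_baseline(bl2, t_s) - lin$values)), 1e-9)
})

test_that("under a flat-plus-noise null, sloping is selected at about alpha", {
  t_s <- seq(20, 600, by = 20)
  tmpl <- structure(list(cycle_times_s = t_s, drug_time_s = 600,
                         baseline_window_s = c(0, 600),
                         valid = rep(TRUE, length(t_s))), class = "dff_series")
  set.seed(1234)
  n_rep <- 2000
  sel <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    d <- tmpl
    d$values <- 0.2 + rnorm(length(t_s), 0, 0.01)
    sel[i] <- fit_baseline(d, alpha = 0.05)$kind == "sloping"
  }
  expect_gt(mean(sel), 0.03)
  expect_lt(mean(sel), 0.07)
})

test_that("short baseline windows are rejected with the 5-min requirement", {
  t_s <- seq(20, 200, by = 20)
  d <- structure(list(values = rep(0.2, length(t_s)), cycle_times_s = t_s,
                      drug_time_s = 200, baseline_window_s = c(0, 200),
                      valid = rep(TRUE, length(t_s))), class = "dff_series")
  expect_error(fit_baseline(d), "5 min")
})

make_series <- function(baseline, post, dt = 20, drug_time_s = NULL) {
  v <- c(baseline, post)
  t_s <- seq_along(v) * dt
  drug_time_s <- drug_time_s %||% (length(baseline) * dt)
  structure(list(values = v, cycle_times_s = t_s, drug_time_s = drug_time_s,
                 baseline_window_s = c(0, drug_time_s),
                 valid = rep(TRUE, length(v))), class = "dff_series")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("responder criterion: sustained 3-SD excursions qualify", {
  set.seed(5)
  baseline <- 0.2 + rnorm(30, 0, 0.01)
  d <- make_series(baseline, rep(0.25, 30))
  bl <- fit_baseline(d)
  call <- detect_responder(d, bl)
  expect_true(call$is_responder)
  expect_equal(call$threshold_used, 3 * bl$baseline_sd)
  # post-drug plateau of 0.25 over a ~0.2 baseline is a ~25% change
  expect_lt(abs(call$percent_change - 100 * (0.25 - bl$baseline_mean) /
                  bl$baseline_mean), 1e-9)
  expect_equal(call$onset_s, 20)

  # same distribution post as pre: not a responder
  d2 <- make_series(baseline, 0.2 + rnorm(30, 0, 0.01))
  call2 <- detect_responder(d2, fit_baseline(d2))
  expect_false(call2$is_responder)
})

test_that("degenerate noiseless baseline: responder by convention, threshold 0", {
  d <- make_series(rep(0.2, 30), rep(0.21, 10))
  bl <- fit_baseline(d)
  expect_equal(bl$baseline_sd, 0)
  call <- detect_responder(d, bl)
  expect_true(call$is_responder)
  expect_equal(call$threshold_used, 0)
})

test_that("null false-positive rate stays below the acceptance bound", {
  set.seed(777)
  n_cells <- 600
  fp <- 0
  for (i in seq_len(n_cells)) {
    d <- make_series(0.2 + rnorm(30, 0, 0.008), 0.2 + rnorm(60, 0, 0.008))
    call <- detect_responder(d, fit_baseline(d))
    fp <- fp + call$is_responder
  }
  expect_lte(fp / n_cells, 0.02)
})

test_that("extraction rejects bad inputs and averages masks correctly", {
  st <- array(7, c(4, 4, 4))
  st[1, 1, ] <- 3; st[2, 1, ] <- 5
  rois <- roi_set(list(c(1L, 2L)), c(4L, 4L), txred_positive = FALSE)
  tr <- extract_roi_traces(st, c(FALSE, TRUE, FALSE, TRUE), rois)
  expect_equal(unname(tr$f1[1, ]), c(4, 4))  # mean of 3 and 5
  expect_equal(unname(tr$f2[1, ]), c(4, 4))

  uniform <- array(7, c(4, 4, 2))
  tru <- extract_roi_traces(uniform, c(FALSE, TRUE),
                            roi_set(list(5:8), c(4L, 4L), FALSE))
  expect_equal(unname(tru$f1[1, 1]), 7)

  expect_error(extract_roi_traces(st, c(TRUE, FALSE, TRUE, FALSE), rois),
               "alternate")
  expect_error(roi_set(list(integer(0)), c(4L, 4L), FALSE), "empty")
})
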