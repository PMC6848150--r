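test_that("static counterstain passes QC; planted z-drift is localised", {
  cfg <- quick_config(seed = 5L)
  sim <- generate_imaging_session(cfg)
  rois <- rois_from_ground_truth(sim$ground_truth)
  tr <- extract_roi_traces(sim$session$cal_stack, sim$session$stim_flags,
                           rois, sim$session$times_s)
  qc <- qc_session(sim$session, rois, tr)
  expect_true(qc$session_pass)

  cfg2 <- quick_config(seed = 5L, z_drift_events = list(c(40, 0.5)))
  sim2 <- generate_imaging_session(cfg2)
  rois2 <- rois_from_ground_truth(sim2$ground_truth)
  tr2 <- extract_roi_traces(sim2$session$cal_stack, sim2$session$stim_flags,
                            rois2, sim2$session$times_s)
  qc2 <- qc_session(sim2$session, rois2, tr2)
  expect_false(qc2$session_pass)
  expect_lte(abs(qc2$drift_frame - 40), 2)
})

test_that("missing counterstain stack makes the session unevaluable", {
  cfg <- quick_config(seed = 6L)
  sim <- generate_imaging_session(cfg)
  rois <- rois_from_ground_truth(sim$ground_truth)
  tr <- extract_roi_traces(sim$session$cal_stack, sim$session$stim_flags,
                           rois, sim$session$times_s)
  broken <- sim$session
  broken$txred_stack <- NULL
  expect_error(qc_session(broken, rois, tr), "counterstain")
})

test_that("counterstain-positive cells are never counted as responders", {
  calls <- data.frame(cell = 1:4, is_responder = c(TRUE, TRUE, FALSE, FALSE),
                      percent_change = c(30, 25, 1, 0),
                      onset_s = c(100, 150, NA, NA),
                      threshold_used = 0.02, baseline_kind = "flat",
                      baseline_sd = 0.005, baseline_mean = 0.2)
  rois <- roi_set(replicate(4, 1L, simplify = FALSE), c(4L, 4L),
                  txred_positive = c(TRUE, FALSE, FALSE, FALSE))
  qc <- structure(list(session_pass = TRUE, responsive = rep(TRUE, 4),
                       vdrn_eligible = c(FALSE, TRUE, TRUE, TRUE)),
                  class = "qc_report")
  s <- summarize_slice(calls, rois, qc, "cond")
  expect_identical(s$n_vdrn, 1L)       # the TxRed-positive responder-like cell is excluded
  expect_identical(s$n_total_cells, 4L)  # ... but stays in the denominator
  expect_equal(s$responding_percent, 25.0)
})

test_that("unresponsive cells leave the denominator with a recorded reason", {
  calls <- data.frame(cell = 1:5, is_responder = c(TRUE, rep(FALSE, 4)),
                      percent_change = 0, onset_s = NA, threshold_used = 0,
                      baseline_kind = "flat", baseline_sd = 0,
                      baseline_mean = 0.2)
  rois <- roi_set(replicate(5, 1L, simplify = FALSE), c(4L, 4L),
                  txred_positive = rep(FALSE, 5),
                  in_focus = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  qc <- structure(list(session_pass = TRUE,
                       responsive = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                       vdrn_eligible = c(TRUE, TRUE, FALSE, TRUE, FALSE)),
                  class = "qc_report")
  s <- summarize_slice(calls, rois, qc)
  expect_identical(s$n_total_cells, 3L)
  expect_identical(unname(s$exclusion_reasons["electrically_unresponsive"]), 1L)
  expect_identical(unname(s$exclusion_reasons["out_of_focus"]), 1L)
})

test_that("zero eligible cells yield a flagged undefined percentage", {
  calls <- data.frame(cell = 1, is_responder = FALSE, percent_change = 0,
                      onset_s = NA, threshold_used = 0,
                      baseline_kind = "flat", baseline_sd = 0,
                      baseline_mean = 0.2)
  rois <- roi_set(list(1L), c(4L, 4L), FALSE, in_focus = FALSE)
  qc <- structure(list(session_pass = TRUE, responsive = TRUE,
                       vdrn_eligible = FALSE), class = "qc_report")
  s <- summarize_slice(calls, rois, qc)
  expect_true(s$undefined_percent)
  expect_true(is.na(s$responding_percent))
})

test_that("denominator rule: full-pool percentage never exceeds the TxRed-negative one", {
  for (seed in 1:4) {
    cfg <- quick_config(seed = 100L + seed, n_cells = 16L,
                        txred_positive_fraction = 0.25,
                        responder_fraction = 2 / 16)
    sim <- generate_imaging_session(cfg)
    rois <- rois_from_ground_truth(sim$ground_truth)
    res <- analyze_imaging_session(sim$session, rois)
    s <- res$summary
    if (!is.na(s$responding_percent) && !is.na(s$responding_percent_neg)) {
      expect_lte(s$responding_percent, s$responding_percent_neg)
    }
  }
})
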