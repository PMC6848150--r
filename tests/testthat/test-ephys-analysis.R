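test_that("P/N scale factor and exact cancellation of linear artifacts", {
  p <- voltage_protocol()
  # -80 -> 0 mV test vs -80 -> -100 mV sub-steps: scale 80 / (-20) = -4
  expect_equal((0 - p$holding_mv) / diff(p$pn_step_mv), -4)

  # pure leak + capacitive sweeps cancel to numerical zero
  m <- channel_model(g_max = 0, g_leak = 2.5, c_membrane = 6, noise_sd = 0)
  e <- generate_ephys_experiment(m, p, 2, 0)
  cs <- correct_sweep_set(e$sweep_set)
  expect_lt(max(abs(cs$sweeps[[1]]$current)), 1e-9)

  expect_error(pn_leak_subtract(e$sweep_set$sweeps[[1]], list(), p, 0),
               "sub-sweep")
  p0 <- voltage_protocol(pn_step_mv = c(-80, -80))
  expect_error(pn_leak_subtract(e$sweep_set$sweeps[[1]],
                                e$sweep_set$pn_sweeps, p0, 0), "nonzero")
})

test_that("P/N subtraction is exact across step amplitudes (linearity)", {
  m <- channel_model(noise_sd = 0, g_leak = 3, c_membrane = 8)
  for (level in c(-60, -30, 0, 20, 40)) {
    p <- voltage_protocol(step_levels_mv = level)
    e <- generate_ephys_experiment(m, p, 1, 0)
    cs <- correct_sweep_set(e$sweep_set)
    sw <- cs$sweeps[[1]]
    on_t <- sw$time_ms - p$pre_ms
    in_step <- on_t >= 0 & on_t < p$step_duration_ms
    expected <- channel_current(m, level, on_t[in_step])
    expect_lt(max(abs(sw$current[in_step] - expected)), 1e-9)
  }
})

test_that("I-V family has 14 levels and matches a fine-grid oracle", {
  p <- voltage_protocol(step_levels_mv = seq(-90, 40, 10))
  m <- channel_model(noise_sd = 0)
  e <- generate_ephys_experiment(m, p, 14, 0)
  iv <- build_iv_curve(correct_sweep_set(e$sweep_set))
  expect_identical(nrow(iv), 14L)
  expect_identical(iv$step_mv, seq(-90, 40, 10))
  expect_false(attr(iv, "gap_flagged"))

  # dense-time-grid oracle per step, written independently of sweep_peak
  for (k in which(iv$step_mv >= -30)) {
    v <- iv$step_mv[k]
    tt <- seq(2, 50, by = 1e-3)
    m_inf <- 1 / (1 + exp(-(v - m$v_half) / m$slope_k))
    i_t <- m$g_max * (m_inf * (1 - exp(-tt / m$tau_activation_ms)))^
      m$p_exponent * (v - m$e_rev)
    oracle <- i_t[which.max(abs(i_t))]
    expect_lt(abs(iv$peak_current[k] - oracle) / max(abs(oracle), 1), 1e-3)
  }

  # bell shape: interior maximum of |peak|
  kmax <- which.max(abs(iv$peak_current))
  expect_gt(kmax, 1L)
  expect_lt(kmax, nrow(iv))
})

test_that("fully activated ohmic model gives a linear I-V crossing at E_rev", {
  p <- voltage_protocol(step_levels_mv = seq(-90, 40, 10))
  m <- channel_model(v_half = -200, slope_k = 1, p_exponent = 1L,
                     tau_activation_ms = 0.1, g_leak = 0, c_membrane = 0,
                     noise_sd = 0, e_rev = 10, g_max = 4)
  e <- generate_ephys_experiment(m, p, 14, 0)
  iv <- build_iv_curve(correct_sweep_set(e$sweep_set))
  fit <- stats::lm(peak_current ~ step_mv, data = iv)
  # the fit is perfect by construction; summary() warns about exactly that
  expect_gt(suppressWarnings(summary(fit)$r.squared), 1 - 1e-9)
  expect_lt(abs(-coef(fit)[1] / coef(fit)[2] - 10), 0.01)
})

test_that("missing step levels are flagged as gaps", {
  p <- voltage_protocol(step_levels_mv = seq(-90, 40, 10))
  m <- channel_model(noise_sd = 0)
  e <- generate_ephys_experiment(m, p, 14, 0)
  ss <- correct_sweep_set(e$sweep_set)
  keep <- ss$step_mv != 0
  ss$sweeps <- ss$sweeps[keep]
  ss$step_mv <- ss$step_mv[keep]
  iv <- build_iv_curve(ss)
  expect_true(attr(iv, "gap_flagged"))
  expect_true(is.na(iv$peak_current[iv$step_mv == 0]))
})

test_that("drug-response classification covers responder, rundown and flat", {
  p <- voltage_protocol()
  r <- drug_response_timecourse(generate_ephys_experiment(
    channel_model(drug_gain = 1.33, noise_sd = 0), p, 6, 60)$sweep_set)
  expect_identical(r$classification, "responder")
  expect_gt(r$percent_change, 0)

  d <- drug_response_timecourse(generate_ephys_experiment(
    channel_model(rundown_rate = 0.01, noise_sd = 0), p, 6, 30)$sweep_set)
  expect_identical(d$classification, "rundown")
  expect_lt(d$percent_change, 0)

  f <- drug_response_timecourse(generate_ephys_experiment(
    channel_model(noise_sd = 0), p, 6, 30)$sweep_set)
  expect_identical(f$classification, "flat")
})

test_that("rundown plus drug response is classified against the rundown trend", {
  m <- channel_model(drug_gain = 1.33, rundown_rate = 0.004, noise_sd = 0)
  r <- drug_response_timecourse(generate_ephys_experiment(
    m, voltage_protocol(), 8, 40)$sweep_set)
  expect_identical(r$classification, "responder")
})

test_that("percent change is invariant to amplifier gain rescaling", {
  m <- channel_model(drug_gain = 1.2, noise_sd = 3, seed = 4L)
  e <- generate_ephys_experiment(m, voltage_protocol(), 6, 24)
  base <- drug_response_timecourse(e$sweep_set)
  for (c_ in c(0.5, 10)) {
    ss <- e$sweep_set
    ss$sweeps <- lapply(ss$sweeps, function(s)
      data.frame(time_ms = s$time_ms, current = c_ * s$current))
    ss$pn_sweeps <- lapply(ss$pn_sweeps, function(s)
      data.frame(time_ms = s$time_ms, current = c_ * s$current))
    scaled <- drug_response_timecourse(ss)
    expect_equal(scaled$percent_change, base$percent_change)
    expect_identical(scaled$classification, base$classification)
  }
})

test_that("classification is stable under <=1 s sweep-time jitter", {
  set.seed(8)
  m <- channel_model(drug_gain = 1.33, noise_sd = 4, seed = 12L)
  e <- generate_ephys_experiment(m, voltage_protocol(), 6, 24)
  base <- drug_response_timecourse(e$sweep_set)
  ss <- e$sweep_set
  ss$start_times_s <- ss$start_times_s + runif(length(ss$start_times_s), -1, 1)
  jit <- drug_response_timecourse(ss)
  expect_identical(jit$classification, base$classification)
})

test_that("missing pre-drug baseline raises an error", {
  m <- channel_model(noise_sd = 0)
  e <- generate_ephys_experiment(m, voltage_protocol(), 2, 10)
  expect_error(drug_response_timecourse(e$sweep_set), "pre-drug")
})
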