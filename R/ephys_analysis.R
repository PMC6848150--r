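# Voltage-clamp sweep analysis: P/N leak subtraction, peak currents, I-V
# curves and drug-response time courses.

#' P/N leak subtraction of one test sweep
#'
#' Averages the P/N sub-sweeps, scales the average by the ratio of the test
#' step amplitude to the P/N sub-step amplitude, and subtracts it from the
#' test sweep. For a -80 to 0 mV test pulse with -80 to -100 mV sub-pulses
#' the scale is `80 / (-20) = -4`. Exact whenever leak and capacitive
#' components are linear in step amplitude.
#'
#' @param test_sweep data frame with `time_ms`, `current`.
#' @param pn_sweeps list of sub-sweep data frames (same time base).
#' @param protocol a [voltage_protocol()].
#' @param step_mv the test sweep's step level, mV.
#' @return corrected sweep data frame.
#' @export
pn_leak_subtract <- function(test_sweep, pn_sweeps, protocol, step_mv) {
  stop_if(length(pn_sweeps) < 1L, "at least one P/N sub-sweep required")
  dv_pn <- protocol$pn_step_mv[2L] - protocol$pn_step_mv[1L]
  stop_if(dv_pn == 0, "P/N step amplitude must be nonzero")
  pn_mean <- rowMeans(vapply(pn_sweeps, function(s) s$current,
                             numeric(nrow(test_sweep))))
  scale <- (step_mv - protocol$holding_mv) / dv_pn
  data.frame(time_ms = test_sweep$time_ms,
             current = test_sweep$current - scale * pn_mean)
}

#' Apply P/N subtraction to every sweep of a set
#'
#' @param sweep_set a `sweep_set`.
#' @return the set with corrected sweeps (and a `corrected = TRUE` marker).
#' @export
correct_sweep_set <- function(sweep_set) {
  sweep_set$sweeps <- lapply(seq_along(sweep_set$sweeps), function(k)
    pn_leak_subtract(sweep_set$sweeps[[k]], sweep_set$pn_sweeps,
                     sweep_set$protocol, sweep_set$step_mv[k]))
  sweep_set$corrected <- TRUE
  sweep_set
}

#' Peak current of one corrected sweep
#'
#' The sweep is pre-smoothed with a `smooth_ms` boxcar and the signed
#' largest-magnitude deflection is taken within the step window, excluding
#' the first `blank_ms` after step onset where residual capacitive transient
#' can survive subtraction.
#'
#' @param sweep corrected sweep data frame.
#' @param protocol a [voltage_protocol()].
#' @param smooth_ms boxcar width, ms (default 2).
#' @param blank_ms post-onset blanking, ms (default 2).
#' @return list with `peak` (signed, pA) and `peak_time_ms` (relative to step
#'   onset).
#' @export
sweep_peak <- function(sweep, protocol, smooth_ms = 2, blank_ms = 2) {
  on_t <- sweep$time_ms - protocol$pre_ms
  idx <- which(on_t >= blank_ms & on_t <= protocol$step_duration_ms)
  stop_if(length(idx) == 0L, "empty peak-search window")
  k <- max(1L, round(smooth_ms * protocol$sampling_khz))
  sm <- boxcar(sweep$current, k)[idx]
  i <- which.max(abs(sm))
  list(peak = sm[i], peak_time_ms = on_t[idx][i])
}

#' Current-voltage curve from a corrected I-V sweep family
#'
#' Expects one P/N-corrected sweep per protocol step level. Missing levels
#' are emitted as `NA` rows with `gap_flagged = TRUE`.
#'
#' @param sweep_set a corrected `sweep_set` (see [correct_sweep_set()]).
#' @param smooth_ms,blank_ms see [sweep_peak()].
#' @return object of class `iv_curve`: data frame `step_mv`, `peak_current`,
#'   `peak_time_ms` ordered by step level, with attribute `gap_flagged`.
#' @export
build_iv_curve <- function(sweep_set, smooth_ms = 2, blank_ms = 2) {
  proto <- sweep_set$protocol
  levels <- sort(unique(proto$step_levels_mv))
  rows <- lapply(levels, function(v) {
    k <- which(sweep_set$step_mv == v)
    if (!length(k)) {
      data.frame(step_mv = v, peak_current = NA_real_, peak_time_ms = NA_real_)
    } else {
      p <- sweep_peak(sweep_set$sweeps[[k[1L]]], proto, smooth_ms, blank_ms)
      data.frame(step_mv = v, peak_current = p$peak,
                 peak_time_ms = p$peak_time_ms)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "gap_flagged") <- anyNA(out$peak_current)
  class(out) <- c("iv_curve", class(out))
  out
}

#' Drug-response time course of a repeated test-pulse experiment
#'
#' Per-sweep peak magnitudes form the time series. The baseline is the mean
#' pre-drug peak magnitude; the onset is the first of at least
#' `onset_min_consecutive` consecutive post-drug sweeps whose peak lies
#' beyond `onset_k_sd` baseline SDs; the percent change compares the plateau
#' (last `plateau_fraction` of the post-drug epoch) against baseline.
#'
#' Because rundown co-occurs with genuine drug responses, classification is
#' decided against the extrapolated pre-drug linear trend: a plateau
#' deviation above the trend beyond noise is a `responder`; otherwise a
#' significantly negative overall slope is `rundown`, else `flat`.
#'
#' @param sweep_set a `sweep_set` (P/N-corrected automatically if not
#'   already).
#' @param onset_k_sd baseline-SD multiplier for onset detection (default 2).
#' @param onset_min_consecutive consecutive supra-threshold sweeps required
#'   (default 2).
#' @param plateau_fraction trailing fraction of the post-drug epoch used as
#'   the plateau window (default 1/3).
#' @param slope_alpha significance level for the rundown slope test.
#' @param smooth_ms,blank_ms see [sweep_peak()].
#' @return object of class `drug_response`: `baseline_peak`,
#'   `percent_change`, `onset_min`, `peak_response_min`, `classification`,
#'   `peaks` (per-sweep magnitudes), `times_s`.
#' @export
drug_response_timecourse <- function(sweep_set, onset_k_sd = 2,
                                     onset_min_consecutive = 2L,
                                     plateau_fraction = 1 / 3,
                                     slope_alpha = 0.05,
                                     smooth_ms = 2, blank_ms = 2) {
  if (!isTRUE(sweep_set$corrected)) sweep_set <- correct_sweep_set(sweep_set)
  proto <- sweep_set$protocol
  peaks <- abs(vapply(sweep_set$sweeps, function(s)
    sweep_peak(s, proto, smooth_ms, blank_ms)$peak, numeric(1)))
  times <- sweep_set$start_times_s
  pre <- which(times < sweep_set$drug_time_s)
  post <- which(times >= sweep_set$drug_time_s)
  stop_if(length(pre) < 3L, "need >= 3 pre-drug sweeps for a baseline")
  stop_if(length(post) < 2L, "need >= 2 post-drug sweeps")

  baseline_peak <- mean(peaks[pre])
  baseline_sd <- stats::sd(peaks[pre])

  # pre-drug linear trend (captures rundown), extrapolated forward
  tc <- times[pre] - mean(times[pre])
  slope_pre <- sum(tc * peaks[pre]) / sum(tc^2)
  trend <- function(t) baseline_peak + slope_pre * (t - mean(times[pre]))

  beyond <- abs(peaks[post] - baseline_peak) > onset_k_sd * baseline_sd
  start <- first_run_start(beyond, onset_min_consecutive)
  onset_min <- if (is.na(start)) NA_real_ else
    (times[post[start]] - sweep_set$drug_time_s) / 60
  peak_response_min <- (times[post[which.max(peaks[post])]] -
                          sweep_set$drug_time_s) / 60

  n_post <- length(post)
  plateau <- post[seq.int(max(1L, n_post - ceiling(plateau_fraction * n_post) + 1L),
                          n_post)]
  percent_change <- 100 * (mean(peaks[plateau]) - baseline_peak) / baseline_peak

  resid_pre <- peaks[pre] - trend(times[pre])
  noise <- max(baseline_sd, stats::sd(resid_pre))
  dev_plateau <- mean(peaks[plateau] - trend(times[plateau]))
  up <- if (noise == 0) dev_plateau > 0 else dev_plateau > onset_k_sd * noise

  classification <- if (up && !is.na(start) &&
                        peaks[post[start]] > baseline_peak) {
    "responder"
  } else {
    # overall slope test on all sweeps
    ta <- times - mean(times)
    sl <- sum(ta * peaks) / sum(ta^2)
    res <- peaks - (mean(peaks) + sl * ta)
    s2 <- sum(res^2) / max(length(peaks) - 2L, 1L)
    se <- sqrt(s2 / sum(ta^2))
    sig_neg <- if (se == 0) sl < 0 else
      (sl < 0 && 2 * stats::pt(-abs(sl / se), length(peaks) - 2L) < slope_alpha)
    if (sig_neg) "rundown" else "flat"
  }
  structure(list(baseline_peak = baseline_peak,
                 percent_change = percent_change, onset_min = onset_min,
                 peak_response_min = peak_response_min,
                 classification = classification, peaks = peaks,
                 times_s = times),
            class = "drug_response")
}
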