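# Responder detection: the k-standard-deviation criterion.
#
# A cell is called a responder when its detrended post-drug delta-F/F exceeds
# k_sd baseline standard deviations for at least min_consecutive consecutive
# stimulation cycles. The persistence requirement separates genuine onsets
# from single-cycle noise excursions at 0.05 Hz.

#' Classify one cell as responder or non-responder
#'
#' Post-drug delta-F/F values are detrended by the extrapolated baseline
#' model and compared against `k_sd * baseline_sd`. The onset is the time of
#' the first cycle of the first qualifying run, relative to drug application.
#' The percent change is the mean detrended deviation over the post-response
#' window (onset to end of recording), expressed as a percentage of the
#' baseline mean.
#'
#' In the degenerate noiseless case (`baseline_sd == 0`) the threshold is 0
#' and any sustained positive deviation qualifies.
#'
#' @param dff a [dff_series][instantaneous_dff()].
#' @param baseline a [baseline_model][fit_baseline()] fitted on the same
#'   series' pre-drug window.
#' @param k_sd threshold multiplier (default 3).
#' @param min_consecutive required consecutive supra-threshold cycles
#'   (default 3, i.e. 60 s at 0.05 Hz).
#' @return object of class `responder_call`: `is_responder`, `percent_change`,
#'   `onset_s` (seconds from drug application; `NA` for non-responders),
#'   `threshold_used` (delta-F/F units).
#' @export
detect_responder <- function(dff, baseline, k_sd = 3, min_consecutive = 3L) {
  check_positive(k_sd, "k_sd")
  stop_if(min_consecutive < 1L, "`min_consecutive` must be >= 1")
  post <- which(dff$valid & dff$cycle_times_s > dff$drug_time_s)
  stop_if(length(post) == 0L, "no valid post-drug cycles")
  t_post <- dff$cycle_times_s[post]
  delta <- dff$values[post] - predict_baseline(baseline, t_post)
  threshold <- k_sd * baseline$baseline_sd
  start <- first_run_start(delta > threshold, min_consecutive)
  is_responder <- !is.na(start)
  if (is_responder) {
    onset_s <- t_post[start] - dff$drug_time_s
    window <- start:length(post)
  } else {
    onset_s <- NA_real_
    window <- seq_along(post)
  }
  percent_change <- 100 * mean(delta[window]) / baseline$baseline_mean
  structure(list(is_responder = is_responder,
                 percent_change = percent_change,
                 onset_s = onset_s, threshold_used = threshold,
                 k_sd = k_sd, min_consecutive = as.integer(min_consecutive)),
            class = "responder_call")
}

#' Responder calls for every cell of a session
#'
#' Convenience wrapper running [instantaneous_dff()], [fit_baseline()] and
#' [detect_responder()] per cell.
#'
#' @param traces an [roi_traces][extract_roi_traces()] object.
#' @param drug_time_s drug application time, seconds.
#' @param k_sd,min_consecutive see [detect_responder()].
#' @param baseline_alpha slope-selection significance level, see
#'   [fit_baseline()].
#' @return data frame with one row per cell: `cell`, `is_responder`,
#'   `percent_change`, `onset_s`, `threshold_used`, `baseline_kind`,
#'   `baseline_sd`, `baseline_mean`.
#' @export
detect_responders <- function(traces, drug_time_s, k_sd = 3,
                              min_consecutive = 3L, baseline_alpha = 0.01) {
  n <- nrow(traces$f1)
  rows <- lapply(seq_len(n), function(i) {
    dff <- instantaneous_dff(roi_trace(traces, i), drug_time_s)
    bl <- fit_baseline(dff, alpha = baseline_alpha)
    call <- detect_responder(dff, bl, k_sd = k_sd,
                             min_consecutive = min_consecutive)
    data.frame(cell = i, is_responder = call$is_responder,
               percent_change = call$percent_change, onset_s = call$onset_s,
               threshold_used = call$threshold_used,
               baseline_kind = bl$kind, baseline_sd = bl$baseline_sd,
               baseline_mean = bl$baseline_mean)
  })
  do.call(rbind, rows)
}
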