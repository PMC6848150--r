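# End-to-end analysis of one imaging session.

#' Imaging-analysis parameters
#'
#' @param radius_px rolling-ball radius in pixels (default 50).
#' @param rb_method rolling-ball mode, see [rolling_ball_background()].
#' @param bg_temporal_bin frames per background-estimation bin (default 10).
#'   The background is a slowly varying nuisance (shading, bleach), so it is
#'   estimated on the temporal mean of each bin of consecutive registered
#'   frames and subtracted from every frame of the bin; this keeps the
#'   per-frame background-estimate noise from inflating the delta-F/F noise
#'   floor. Set to 1 for strictly per-frame estimation.
#' @param register estimate and correct XY translation (default `TRUE`).
#' @param k_sd,min_consecutive responder criterion, see [detect_responder()].
#' @param baseline_alpha slope-selection level, see [fit_baseline()].
#' @param drift_threshold,responsiveness_k QC settings, see [qc_session()].
#' @return list of class `analysis_params`.
#' @export
analysis_params <- function(radius_px = 50, rb_method = "auto",
                            bg_temporal_bin = 10L,
                            register = TRUE, k_sd = 3, min_consecutive = 3L,
                            baseline_alpha = 0.01, drift_threshold = 0.10,
                            responsiveness_k = 2) {
  structure(as.list(environment()), class = "analysis_params")
}

#' Analyse one imaging session end to end
#'
#' Pipeline: XY registration of the indicator stack, per-frame rolling-ball
#' background subtraction, ROI trace extraction, per-cell instantaneous
#' delta-F/F with flat-or-sloping baselining and the k-SD responder
#' criterion, session QC on the counterstain channel, and a slice summary.
#'
#' @param session an `imaging_session` (see [generate_imaging_session()] or
#'   [read_imaging_session()]).
#' @param rois an [roi_set()].
#' @param params an [analysis_params()].
#' @return list with `summary` ([summarize_slice()]), `calls`
#'   ([detect_responders()] data frame), `traces`, `qc`, `shifts`.
#' @export
analyze_imaging_session <- function(session, rois, params = analysis_params()) {
  stack <- session$cal_stack
  shifts <- NULL
  if (isTRUE(params$register)) {
    reg <- register_translation(stack)
    stack <- reg$corrected
    shifts <- reg$shifts
  }
  nt <- dim(stack)[3L]
  bin <- max(1L, as.integer(params$bg_temporal_bin %||% 1L))
  for (g in split(seq_len(nt), ceiling(seq_len(nt) / bin))) {
    avg <- if (length(g) > 1L)
      rowMeans(matrix(stack[, , g], ncol = length(g)), dims = 1L) else
        as.vector(stack[, , g])
    avg <- matrix(avg, dim(stack)[1L], dim(stack)[2L])
    bg <- rolling_ball_background(avg, radius_px = params$radius_px,
                                  method = params$rb_method)
    for (f in g) stack[, , f] <- pmax(stack[, , f] - pmin(bg, stack[, , f]), 0)
  }
  traces <- extract_roi_traces(stack, session$stim_flags, rois,
                               session$times_s)
  calls <- detect_responders(traces, session$drug_time_s,
                             k_sd = params$k_sd,
                             min_consecutive = params$min_consecutive,
                             baseline_alpha = params$baseline_alpha)
  # QC uses raw traces/counterstain: responsiveness and drift are properties
  # of the acquisition, not of the background model.
  raw_traces <- extract_roi_traces(session$cal_stack, session$stim_flags,
                                   rois, session$times_s)
  qc <- qc_session(session, rois, raw_traces,
                   drift_threshold = params$drift_threshold,
                   responsiveness_k = params$responsiveness_k)
  summary <- summarize_slice(calls, rois, qc, session$condition_label)
  list(summary = summary, calls = calls, traces = traces, qc = qc,
       shifts = shifts)
}
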