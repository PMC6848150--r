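# Session and cell quality control.
#
# Two gates mirror routine practice in stimulus-locked slice imaging:
# (a) whole-session exclusion when the counterstain channel shows a sustained
#     change in sharpness/intensity (the signature of focal-plane z-drift),
# (b) per-cell eligibility: a cell must be electrically responsive in the
#     baseline window; counterstain-positive cells stay in denominators but
#     can never be counted as responders.

# High-frequency energy of a frame: mean squared residual after a 3x3 blur.
# Blurring or attenuating fine structure lowers it.
hf_energy <- function(img) {
  mean((img - gaussian_blur(img, 0.8))^2)
}

#' Session QC: z-drift screening and cell eligibility
#'
#' The z-drift metric is the relative change of each counterstain frame's
#' high-frequency energy against the first frame; a change beyond
#' `drift_threshold` sustained for at least `drift_min_frames` frames flags
#' the whole session for exclusion. Electrical responsiveness requires the
#' baseline-window mean delta-F/F to exceed `responsiveness_k` times the
#' pooled per-cycle noise SD (estimated from cycle-to-cycle differences of
#' resting fluorescence, which carry no stimulus signal).
#'
#' @param session an `imaging_session`.
#' @param rois an [roi_set()].
#' @param traces an [roi_traces][extract_roi_traces()] for the same cells.
#' @param drift_threshold relative high-frequency energy change (default 0.10).
#' @param drift_min_frames frames the change must persist (default 2).
#' @param responsiveness_k noise-floor multiplier (default 2).
#' @return object of class `qc_report`: `session_pass`, `drift_frame`,
#'   `drift_metric` (per frame), `responsive` and `vdrn_eligible` (per cell),
#'   `noise_sd_dff` (pooled per-cycle delta-F/F noise SD).
#' @export
qc_session <- function(session, rois, traces, drift_threshold = 0.10,
                       drift_min_frames = 2L, responsiveness_k = 2) {
  stop_if(is.null(session$txred_stack),
          "counterstain stack missing: session cannot be QC-evaluated")
  tx <- session$txred_stack
  nt <- dim(tx)[3L]
  e <- vapply(seq_len(nt), function(f) hf_energy(tx[, , f]), numeric(1))
  drift_metric <- abs(e / e[1L] - 1)
  exceed <- drift_metric > drift_threshold
  start <- first_run_start(exceed, drift_min_frames)
  session_pass <- is.na(start)
  drift_frame <- if (session_pass) NA_integer_ else as.integer(start)

  baseline_idx <- which(traces$cycle_times_s <= session$drug_time_s)
  dff_baseline <- (traces$f2[, baseline_idx, drop = FALSE] -
                     traces$f1[, baseline_idx, drop = FALSE]) /
    traces$f1[, baseline_idx, drop = FALSE]
  mean_dff <- rowMeans(dff_baseline)
  per_cell_noise <- apply(dff_baseline, 1L, function(v)
    stats::sd(diff(v)) / sqrt(2))
  noise_sd_dff <- stats::median(per_cell_noise, na.rm = TRUE)
  responsive <- mean_dff > responsiveness_k * noise_sd_dff
  vdrn_eligible <- responsive & !rois$txred_positive & rois$in_focus

  structure(list(session_pass = session_pass, drift_frame = drift_frame,
                 drift_metric = drift_metric, responsive = responsive,
                 vdrn_eligible = vdrn_eligible, noise_sd_dff = noise_sd_dff,
                 drift_threshold = drift_threshold,
                 responsiveness_k = responsiveness_k),
            class = "qc_report")
}
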