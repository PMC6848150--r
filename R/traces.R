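# ROI trace extraction and the instantaneous delta-F/F statistic.
#
# Frames alternate unstimulated / stimulated. Each consecutive
# (unstimulated F1, stimulated F2) pair is one stimulation cycle; the
# per-cycle activity statistic is (F2 - F1) / F1.

#' Construct an ROI set
#'
#' @param masks list of integer vectors of linear pixel indices (column-major,
#'   1-based) into a `dim[1] x dim[2]` frame, one per cell.
#' @param dim image dimensions `c(height, width)`.
#' @param txred_positive logical per cell: counterstain-positive (putative
#'   glia, ineligible as responders but retained in denominators).
#' @param in_focus logical per cell (default all `TRUE`).
#' @return object of class `roi_set`.
#' @export
roi_set <- function(masks, dim, txred_positive, in_focus = NULL) {
  n <- length(masks)
  stop_if(n == 0L, "`masks` must contain at least one ROI")
  stop_if(any(vapply(masks, length, 1L) == 0L), "empty ROI mask")
  stop_if(length(txred_positive) != n, "one txred label per cell required")
  in_focus <- in_focus %||% rep(TRUE, n)
  stop_if(length(in_focus) != n, "one in_focus flag per cell required")
  structure(list(masks = masks, dim = as.integer(dim),
                 txred_positive = as.logical(txred_positive),
                 in_focus = as.logical(in_focus)),
            class = "roi_set")
}

check_alternating <- function(stim_flags) {
  nt <- length(stim_flags)
  stop_if(nt %% 2L != 0L || !identical(as.logical(stim_flags),
                                       rep(c(FALSE, TRUE), nt %/% 2L)),
          "stim_flags must strictly alternate FALSE/TRUE starting unstimulated")
}

#' Extract per-cell F1/F2 trace pairs from a preprocessed stack
#'
#' Computes the mean masked intensity of every ROI in every frame, then pairs
#' frames into stimulation cycles: each unstimulated frame (F1) with the
#' immediately following stimulated frame (F2). The cycle time is the
#' stimulated frame's acquisition time. Cycles are never re-paired across a
#' dropped frame: pairing is positional on the alternating flags.
#'
#' @param cal_stack indicator-channel stack (height x width x frames),
#'   background-subtracted and registered upstream.
#' @param stim_flags logical per frame, strictly alternating, first frame
#'   unstimulated.
#' @param rois an [roi_set()].
#' @param times_s per-frame acquisition times in seconds.
#' @return object of class `roi_traces`: matrices `f1`, `f2`
#'   (cells x cycles) and `cycle_times_s`.
#' @export
extract_roi_traces <- function(cal_stack, stim_flags, rois, times_s = NULL) {
  stop_if(!inherits(rois, "roi_set"), "`rois` must be an roi_set")
  d <- dim(cal_stack)
  stop_if(length(d) != 3L, "`cal_stack` must be an H x W x T array")
  stop_if(!identical(d[1:2], rois$dim), "ROI dimensions do not match the stack")
  check_alternating(stim_flags)
  nt <- d[3L]
  times_s <- times_s %||% (seq_len(nt) - 1)
  stop_if(length(times_s) != nt, "one time per frame required")
  stop_if(any(diff(times_s) <= 0), "times_s must be strictly increasing")

  flat <- matrix(cal_stack, d[1L] * d[2L], nt)
  means <- t(vapply(rois$masks, function(idx)
    colMeans(flat[idx, , drop = FALSE]), numeric(nt)))
  structure(list(f1 = means[, !stim_flags, drop = FALSE],
                 f2 = means[, stim_flags, drop = FALSE],
                 cycle_times_s = times_s[stim_flags]),
            class = "roi_traces")
}

#' Single-cell trace accessor
#'
#' @param traces an `roi_traces` object from [extract_roi_traces()].
#' @param cell cell index.
#' @return object of class `roi_trace` with `f1_series`, `f2_series`,
#'   `cycle_times_s`.
#' @export
roi_trace <- function(traces, cell) {
  structure(list(f1_series = traces$f1[cell, ], f2_series = traces$f2[cell, ],
                 cycle_times_s = traces$cycle_times_s),
            class = "roi_trace")
}

#' Instantaneous delta-F/F series for one cell
#'
#' `values[i] = (F2[i] - F1[i]) / F1[i]` per stimulation cycle. Cycles with
#' nonpositive resting fluorescence have no defined ratio; they are flagged
#' invalid (`NA` value) and excluded from all downstream windows.
#'
#' @param trace an [roi_trace()] (or any list with `f1_series`, `f2_series`,
#'   `cycle_times_s`).
#' @param drug_time_s bath-application time of the drug, seconds.
#' @param baseline_window_s numeric `c(start, end)` seconds; defaults to the
#'   whole pre-drug epoch `c(0, drug_time_s)`.
#' @return object of class `dff_series` with `values`, `cycle_times_s`,
#'   `drug_time_s`, `baseline_window_s`, `valid`.
#' @export
instantaneous_dff <- function(trace, drug_time_s, baseline_window_s = NULL) {
  f1 <- trace$f1_series; f2 <- trace$f2_series
  stop_if(length(f1) != length(f2), "F1/F2 series lengths differ")
  valid <- is.finite(f1) & is.finite(f2) & f1 > 0
  values <- rep(NA_real_, length(f1))
  values[valid] <- (f2[valid] - f1[valid]) / f1[valid]
  baseline_window_s <- baseline_window_s %||% c(0, drug_time_s)
  stop_if(baseline_window_s[2L] > drug_time_s,
          "baseline window must precede drug application")
  structure(list(values = values, cycle_times_s = trace$cycle_times_s,
                 drug_time_s = drug_time_s,
                 baseline_window_s = baseline_window_s, valid = valid),
            class = "dff_series")
}
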