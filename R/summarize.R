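# Per-slice summary with the conservative denominator rule.

#' Summarise responder calls for one imaged slice
#'
#' The responding percentage uses the conservative denominator: all in-focus,
#' electrically responsive indicator-positive cells, counterstain-positive
#' and -negative alike. Responders themselves are counted only among
#' counterstain-negative eligible cells, so the reported proportion can only
#' underestimate the fraction of neurons that responded.
#'
#' @param calls data frame from [detect_responders()].
#' @param rois an [roi_set()].
#' @param qc a [qc_report][qc_session()].
#' @param condition_label condition tag carried into the summary.
#' @return object of class `slice_summary`: `condition_label`,
#'   `n_total_cells`, `n_vdrn`, `responding_percent` (1 decimal; `NA` with
#'   `undefined_percent = TRUE` when no cells are eligible), `excluded_cells`,
#'   `exclusion_reasons`, `session_qc_pass`, plus `responding_percent_neg`
#'   (counterstain-negative denominator, for the underestimation property)
#'   and per-responder `percent_change`/`onset_s` vectors.
#' @export
summarize_slice <- function(calls, rois, qc, condition_label = "") {
  n <- nrow(calls)
  stop_if(n != length(rois$txred_positive), "calls and ROI set size differ")
  in_focus <- rois$in_focus
  responsive <- qc$responsive
  counted <- in_focus & responsive
  n_total <- sum(counted)
  vdrn <- calls$is_responder & qc$vdrn_eligible
  n_vdrn <- sum(vdrn)
  excluded <- !counted
  reasons <- c(out_of_focus = sum(!in_focus),
               electrically_unresponsive = sum(in_focus & !responsive))
  undefined <- n_total == 0L
  pct <- if (undefined) NA_real_ else proportion_responding(n_vdrn, n_total)
  n_neg <- sum(counted & !rois$txred_positive)
  pct_neg <- if (n_neg == 0L) NA_real_ else proportion_responding(n_vdrn, n_neg)
  structure(list(condition_label = condition_label,
                 n_total_cells = n_total, n_vdrn = n_vdrn,
                 responding_percent = pct,
                 responding_percent_neg = pct_neg,
                 excluded_cells = sum(excluded), exclusion_reasons = reasons,
                 undefined_percent = undefined,
                 session_qc_pass = qc$session_pass,
                 responder_percent_change = calls$percent_change[vdrn],
                 responder_onset_s = calls$onset_s[vdrn]),
            class = "slice_summary")
}
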