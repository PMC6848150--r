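# Baseline modelling of the pre-drug delta-F/F epoch.
#
# The pre-drug window is summarised by either a flat (constant) or a sloping
# (least-squares line) baseline, extrapolated across the post-drug epoch for
# detrending. The sloping model is selected only when the slope is
# statistically significant, so that noise alone keeps the flat model.

#' Fit a flat-or-sloping baseline model to the pre-drug window
#'
#' Fits both a constant and a least-squares line to the delta-F/F values in
#' the baseline window and keeps the sloping model only when the slope's
#' t-test is significant at `alpha` (a noiseless nonzero slope always counts
#' as significant). The default `alpha = 0.01` is deliberately strict: a
#' noise-selected slope gets extrapolated across the whole post-drug epoch,
#' where even a small spurious slope drifts the detrended series past a k-SD
#' threshold and inflates the responder false-positive rate well beyond
#' `alpha` itself; genuine baseline drifts yield far smaller p values and
#' are still selected. The >=5-minute window requirement mirrors the
#' responder-criterion definition: thresholds are multiples of the baseline
#' SD, which needs a sufficiently long window to estimate.
#'
#' @param dff a [dff_series][instantaneous_dff()].
#' @param alpha significance level for slope selection (default 0.01).
#' @param min_window_s minimum baseline window span in seconds (default 300).
#' @return object of class `baseline_model`: `kind` ("flat"/"sloping"),
#'   `intercept`, `slope` (delta-F/F per second), `baseline_sd` (SD of
#'   residuals from the selected model), `baseline_mean`, `slope_p`, `n`.
#' @export
fit_baseline <- function(dff, alpha = 0.01, min_window_s = 300) {
  win <- dff$baseline_window_s
  idx <- which(dff$valid & dff$cycle_times_s >= win[1L] &
                 dff$cycle_times_s <= win[2L])
  stop_if(length(idx) < 2L, "baseline window contains < 2 valid cycles")
  stop_if(win[2L] - win[1L] < min_window_s,
          paste0("baseline window spans %.0f s; the responder criterion ",
                 "requires a pre-drug baseline of at least %.0f s (5 min)"),
          win[2L] - win[1L], min_window_s)
  t_ <- dff$cycle_times_s[idx]
  y <- dff$values[idx]
  n <- length(y)
  tc <- t_ - mean(t_)
  sxx <- sum(tc^2)
  slope <- sum(tc * y) / sxx
  mu <- mean(y)
  resid_line <- y - (mu + slope * tc)
  s2 <- sum(resid_line^2) / max(n - 2L, 1L)
  se <- sqrt(s2 / sxx)
  slope_p <- if (se == 0) {
    if (slope == 0) 1 else 0
  } else {
    2 * stats::pt(-abs(slope / se), df = n - 2L)
  }
  sloping <- slope_p < alpha
  if (sloping) {
    intercept <- mu - slope * mean(t_)
    resid <- resid_line
  } else {
    slope <- 0
    intercept <- mu
    resid <- y - mu
  }
  baseline_sd <- stats::sd(resid)
  structure(list(kind = if (sloping) "sloping" else "flat",
                 intercept = intercept, slope = slope,
                 baseline_sd = baseline_sd, baseline_mean = mu,
                 slope_p = slope_p, n = n, window_s = win, alpha = alpha),
            class = "baseline_model")
}

#' Evaluate a baseline model at given times
#'
#' @param model a [baseline_model][fit_baseline()].
#' @param times_s times in seconds.
#' @return predicted baseline delta-F/F at `times_s`.
#' @export
predict_baseline <- function(model, times_s) {
  model$intercept + model$slope * times_s
}
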