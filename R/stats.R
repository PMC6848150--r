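# Group statistics: Welch's unequal-variance t test and responder
# proportions.

#' Welch's unpaired two-tailed t test
#'
#' `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-tailed p value from the
#' t distribution. With zero variance in both samples and equal means the
#' statistic is undefined and reported as `NA`.
#'
#' @param sample_a,sample_b numeric vectors (each of length >= 2, finite).
#' @param label_a,label_b group labels carried into the result.
#' @return object of class `group_comparison`: `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `sem_a`, `sem_b`, `t_stat`, `df_welch`, `p_two_tailed`.
#' @export
welch_t_test <- function(sample_a, sample_b, label_a = "A", label_b = "B") {
  stop_if(length(sample_a) < 2L || length(sample_b) < 2L,
          "each sample needs >= 2 observations")
  stop_if(!all(is.finite(sample_a)) || !all(is.finite(sample_b)),
          "samples must be finite")
  n_a <- length(sample_a); n_b <- length(sample_b)
  m_a <- mean(sample_a); m_b <- mean(sample_b)
  v_a <- stats::var(sample_a); v_b <- stats::var(sample_b)
  se2 <- v_a / n_a + v_b / n_b
  if (se2 == 0) {
    t_stat <- if (m_a == m_b) NA_real_ else sign(m_a - m_b) * Inf
    df <- NA_real_
    p <- if (m_a == m_b) NA_real_ else 0
  } else {
    t_stat <- (m_a - m_b) / sqrt(se2)
    df <- se2^2 / ((v_a / n_a)^2 / (n_a - 1L) + (v_b / n_b)^2 / (n_b - 1L))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(group_a_label = label_a, group_b_label = label_b,
                 n_a = n_a, n_b = n_b, mean_a = m_a, mean_b = m_b,
                 sem_a = sqrt(v_a / n_a), sem_b = sqrt(v_b / n_b),
                 t_stat = t_stat, df_welch = df, p_two_tailed = p),
            class = "group_comparison")
}

#' Responding percentage from counts
#'
#' `100 * n_responders / n_total`, reported to `digits` decimals (default 1,
#' matching how slice proportions are conventionally reported; pass
#' `digits = NULL` for the unrounded value).
#'
#' @param n_responders,n_total nonnegative counts with
#'   `n_responders <= n_total` and `n_total > 0`.
#' @param digits decimal places (default 1; `NULL` = no rounding).
#' @return percentage in `[0, 100]`.
#' @export
proportion_responding <- function(n_responders, n_total, digits = 1L) {
  stop_if(n_total <= 0, "n_total must be > 0")
  stop_if(n_responders < 0 || n_responders > n_total,
          "n_responders must be in [0, n_total]")
  pct <- 100 * n_responders / n_total
  if (is.null(digits)) pct else round(pct, digits)
}
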