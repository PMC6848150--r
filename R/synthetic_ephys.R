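# Synthetic nucleated-patch voltage-clamp experiments.
#
# Macroscopic high-voltage-activated current model: Boltzmann steady-state
# activation with first-order kinetics, plus the artifacts the analysis has
# to cope with -- linear leak, biexponential capacitive transients at step
# edges, geometric per-sweep rundown, and a saturating drug-evoked
# conductance increase. P/N sub-sweeps contain only the linear components,
# which is exactly the assumption P/N subtraction rests on.

#' Channel model for the sweep generator
#'
#' @param g_max maximal conductance, nS.
#' @param v_half half-activation voltage, mV.
#' @param slope_k Boltzmann slope factor, mV (> 0).
#' @param p_exponent activation-gate exponent (integer >= 1).
#' @param e_rev reversal potential, mV.
#' @param tau_activation_ms first-order activation time constant, ms.
#' @param g_leak linear leak conductance, nS.
#' @param c_membrane membrane capacitance scale for the transients, pF.
#' @param rundown_rate fractional conductance loss per sweep in [0, 1).
#' @param drug_gain asymptotic multiplicative conductance gain after drug
#'   onset (> 0; 1 means no drug effect).
#' @param drug_onset_s drug application time, seconds (`NULL`: set by the
#'   experiment generator to the end of the baseline epoch).
#' @param drug_tau_s time constant of the saturating drug effect, seconds.
#' @param noise_sd per-sample Gaussian current noise SD, pA.
#' @param seed integer RNG seed.
#' @return object of class `channel_model`.
#' @export
channel_model <- function(g_max = 8, v_half = -10, slope_k = 6,
                          p_exponent = 2L, e_rev = 60,
                          tau_activation_ms = 1.5, g_leak = 2,
                          c_membrane = 5, rundown_rate = 0, drug_gain = 1,
                          drug_onset_s = NULL, drug_tau_s = 100,
                          noise_sd = 0, seed = 1L) {
  check_positive(slope_k, "slope_k")
  check_positive(g_max, "g_max", strict = FALSE)
  check_positive(drug_gain, "drug_gain")
  check_positive(tau_activation_ms, "tau_activation_ms")
  check_positive(drug_tau_s, "drug_tau_s")
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  stop_if(rundown_rate < 0 || rundown_rate >= 1,
          "rundown_rate must be in [0, 1)")
  stop_if(p_exponent < 1L, "p_exponent must be >= 1")
  structure(as.list(environment()), class = "channel_model")
}

#' Voltage-step protocol description
#'
#' @param holding_mv holding potential, mV.
#' @param step_levels_mv step level(s), mV; a single level describes a
#'   repeated test pulse, multiple levels an I-V family.
#' @param step_duration_ms step duration, ms.
#' @param pre_ms,post_ms holding segments before/after the step, ms.
#' @param inter_sweep_interval_s seconds between sweep starts.
#' @param pn_n_reps number of P/N sub-sweeps (>= 1).
#' @param pn_step_mv P/N sub-step `c(from, to)`, mV.
#' @param sampling_khz sampling rate, kHz.
#' @return object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(holding_mv = -80, step_levels_mv = 0,
                             step_duration_ms = 50, pre_ms = 10, post_ms = 10,
                             inter_sweep_interval_s = 20, pn_n_reps = 15L,
                             pn_step_mv = c(-80, -100), sampling_khz = 20) {
  check_positive(step_duration_ms, "step_duration_ms")
  check_positive(sampling_khz, "sampling_khz")
  check_positive(inter_sweep_interval_s, "inter_sweep_interval_s")
  stop_if(pn_n_reps < 1L, "pn_n_reps must be >= 1")
  stop_if(length(pn_step_mv) != 2L, "pn_step_mv must be c(from, to)")
  structure(as.list(environment()), class = "voltage_protocol")
}

#' Macroscopic channel current at a voltage step
#'
#' Returns `g_max * m(t)^p * (v - e_rev)` where `m(t)` relaxes first-order
#' from 0 toward the Boltzmann steady state
#' `m_inf(v) = 1 / (1 + exp(-(v - v_half) / slope_k))` with time constant
#' `tau_activation_ms`. Leak and noise are excluded (added separately by the
#' sweep generator).
#'
#' @param model a [channel_model()].
#' @param v_mv step voltage, mV.
#' @param t_ms time since step onset, ms (vectorised; must be >= 0).
#' @return current in pA (inward negative), same length as `t_ms`.
#' @export
channel_current <- function(model, v_mv, t_ms) {
  stop_if(any(t_ms < 0), "t_ms must be >= 0")
  m_inf <- 1 / (1 + exp(-(v_mv - model$v_half) / model$slope_k))
  m <- m_inf * (1 - exp(-t_ms / model$tau_activation_ms))
  model$g_max * m^model$p_exponent * (v_mv - model$e_rev)
}

# Biexponential capacitive transient kernel, linear in the voltage jump.
cap_transient <- function(model, t_ms, dv_mv) {
  model$c_membrane * dv_mv *
    (0.7 * exp(-t_ms / 0.2) / 0.2 + 0.3 * exp(-t_ms / 1.0))
}

# Leak + capacitive artifact trace for a step of amplitude dv (linear in dv).
linear_artifact <- function(model, protocol, dv_mv) {
  dt <- 1 / protocol$sampling_khz
  n <- round((protocol$pre_ms + protocol$step_duration_ms + protocol$post_ms) /
               dt)
  t_ms <- (seq_len(n) - 1) * dt
  on_t <- t_ms - protocol$pre_ms
  off_t <- t_ms - protocol$pre_ms - protocol$step_duration_ms
  in_step <- on_t >= 0 & off_t < 0
  cur <- numeric(n)
  cur[in_step] <- model$g_leak * dv_mv
  cur[on_t >= 0] <- cur[on_t >= 0] + cap_transient(model, on_t[on_t >= 0], dv_mv)
  cur[off_t >= 0] <- cur[off_t >= 0] + cap_transient(model, off_t[off_t >= 0], -dv_mv)
  list(t_ms = t_ms, current = cur, in_step = in_step, on_t = on_t)
}

drug_factor <- function(model, t_s, onset_s) {
  ifelse(t_s >= onset_s,
         1 + (model$drug_gain - 1) * (1 - exp(-(t_s - onset_s) / model$drug_tau_s)),
         1)
}

#' Generate a voltage-clamp sweep experiment with ground truth
#'
#' Produces `n_baseline_sweeps + n_post_sweeps` test sweeps at the protocol's
#' step level(s) (recycled across sweeps, so an I-V family is one sweep per
#' level), each the sum of the channel current, linear leak, capacitive
#' transients and Gaussian noise. The effective conductance of sweep `k`
#' starting at time `t` is
#' `g_max * (1 - rundown_rate)^(k-1) * drug_factor(t)`. P/N sub-sweeps
#' contain only the linear components at the sub-step amplitude.
#'
#' @param model a [channel_model()].
#' @param protocol a [voltage_protocol()].
#' @param n_baseline_sweeps,n_post_sweeps sweep counts before/after drug
#'   onset (each >= 1 for the time-course protocol; `n_post_sweeps = 0` is
#'   allowed for drug-free I-V families).
#' @return list with `sweep_set` (class `sweep_set`: `sweeps` list of
#'   data frames `time_ms`/`current`, `step_mv`, `start_times_s`, `protocol`,
#'   `pn_sweeps`, `drug_time_s`) and `ground_truth` (per-sweep effective
#'   conductance and the planted drug onset).
#' @export
generate_ephys_experiment <- function(model, protocol,
                                      n_baseline_sweeps = 6L,
                                      n_post_sweeps = 30L) {
  stop_if(!inherits(model, "channel_model"), "`model` must be a channel_model")
  stop_if(!inherits(protocol, "voltage_protocol"),
          "`protocol` must be a voltage_protocol")
  stop_if(n_baseline_sweeps < 1L, "need at least one baseline sweep")
  stop_if(n_post_sweeps < 0L, "n_post_sweeps must be >= 0")
  n_sweeps <- n_baseline_sweeps + n_post_sweeps
  levels <- rep_len(protocol$step_levels_mv, n_sweeps)
  start_times <- (seq_len(n_sweeps) - 1) * protocol$inter_sweep_interval_s
  drug_time_s <- model$drug_onset_s %||%
    (n_baseline_sweeps * protocol$inter_sweep_interval_s)

  g_eff <- model$g_max * (1 - model$rundown_rate)^(seq_len(n_sweeps) - 1) *
    drug_factor(model, start_times, drug_time_s)

  with_seed(model$seed, {
    sweeps <- vector("list", n_sweeps)
    for (k in seq_len(n_sweeps)) {
      dv <- levels[k] - protocol$holding_mv
      art <- linear_artifact(model, protocol, dv)
      cur <- art$current
      m_k <- model
      m_k$g_max <- g_eff[k]
      cur[art$in_step] <- cur[art$in_step] +
        channel_current(m_k, levels[k], art$on_t[art$in_step])
      if (model$noise_sd > 0)
        cur <- cur + stats::rnorm(length(cur), 0, model$noise_sd)
      sweeps[[k]] <- data.frame(time_ms = art$t_ms, current = cur)
    }
    dv_pn <- protocol$pn_step_mv[2L] - protocol$pn_step_mv[1L]
    pn_sweeps <- lapply(seq_len(protocol$pn_n_reps), function(i) {
      art <- linear_artifact(model, protocol, dv_pn)
      cur <- art$current
      if (model$noise_sd > 0)
        cur <- cur + stats::rnorm(length(cur), 0, model$noise_sd)
      data.frame(time_ms = art$t_ms, current = cur)
    })
    sweep_set <- structure(list(sweeps = sweeps, step_mv = levels,
                                start_times_s = start_times,
                                protocol = protocol, pn_sweeps = pn_sweeps,
                                drug_time_s = drug_time_s),
                           class = "sweep_set")
    ground_truth <- list(g_eff = g_eff, drug_onset_s = drug_time_s,
                         model = model)
    list(sweep_set = sweep_set, ground_truth = ground_truth)
  })
}
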