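# Group-level reporting and whole-study orchestration.

format_p <- function(p) {
  if (is.na(p)) return("NA")
  if (p < 1e-4) return("p < 0.0001")
  sprintf("p = %.2g", p)
}

#' Build a report bundle from slice summaries
#'
#' Emits a per-condition table (slice counts, pooled responder counts and
#' percentages, per-cell percent-change and onset means with SEM), pairwise
#' Welch comparisons between conditions on the slice responding percentages
#' and on per-cell percent changes and onsets, and a human-readable text
#' summary. Ordering is deterministic (alphabetical by condition label).
#'
#' @param summaries list of [slice_summary][summarize_slice()] objects.
#' @param out_dir if not `NULL`, writes `condition_summary.csv`,
#'   `comparisons.csv` and `report.txt` there.
#' @return list with `condition_table`, `comparison_table`, `text` (character
#'   vector of report lines).
#' @export
build_report <- function(summaries, out_dir = NULL) {
  stop_if(length(summaries) < 1L, "at least one slice summary required")
  labels <- sort(unique(vapply(summaries, function(s) s$condition_label,
                               character(1))))
  per_cond <- lapply(labels, function(lab) {
    ss <- Filter(function(s) identical(s$condition_label, lab), summaries)
    pcts <- vapply(ss, function(s) s$responding_percent, numeric(1))
    amp <- unlist(lapply(ss, function(s) s$responder_percent_change))
    onset <- unlist(lapply(ss, function(s) s$responder_onset_s)) / 60
    n_vdrn <- sum(vapply(ss, function(s) s$n_vdrn, numeric(1)))
    n_total <- sum(vapply(ss, function(s) s$n_total_cells, numeric(1)))
    sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
    list(row = data.frame(
      condition = lab, n_slices = length(ss),
      n_vdrn = n_vdrn, n_total_cells = n_total,
      pooled_responding_percent = if (n_total > 0)
        proportion_responding(n_vdrn, n_total) else NA_real_,
      slice_percent_mean = mean(pcts, na.rm = TRUE),
      slice_percent_sem = sem(pcts[!is.na(pcts)]),
      amplitude_mean = if (length(amp)) mean(amp) else NA_real_,
      amplitude_sem = sem(amp),
      onset_min_mean = if (length(onset)) mean(onset) else NA_real_,
      onset_min_sem = sem(onset)),
      pcts = pcts, amp = amp, onset = onset)
  })
  names(per_cond) <- labels
  condition_table <- do.call(rbind, lapply(per_cond, `[[`, "row"))
  rownames(condition_table) <- NULL

  comparison_rows <- list()
  if (length(labels) >= 2L) {
    pairs <- utils::combn(labels, 2L, simplify = FALSE)
    for (pr in pairs) {
      a <- per_cond[[pr[1L]]]; b <- per_cond[[pr[2L]]]
      for (measure in c("pcts", "amp", "onset")) {
        xa <- a[[measure]][is.finite(a[[measure]])]
        xb <- b[[measure]][is.finite(b[[measure]])]
        if (length(xa) >= 2L && length(xb) >= 2L) {
          w <- welch_t_test(xa, xb, pr[1L], pr[2L])
          comparison_rows[[length(comparison_rows) + 1L]] <- data.frame(
            measure = c(pcts = "slice_responding_percent",
                        amp = "cell_percent_change",
                        onset = "cell_onset_min")[[measure]],
            group_a = pr[1L], group_b = pr[2L], n_a = w$n_a, n_b = w$n_b,
            mean_a = w$mean_a, mean_b = w$mean_b,
            sem_a = w$sem_a, sem_b = w$sem_b,
            t_stat = w$t_stat, df_welch = w$df_welch,
            p_two_tailed = w$p_two_tailed)
        }
      }
    }
  }
  comparison_table <- if (length(comparison_rows))
    do.call(rbind, comparison_rows) else
      data.frame(measure = character(), group_a = character(),
                 group_b = character())

  text <- c("Responder screening report", "==========================", "")
  for (i in seq_len(nrow(condition_table))) {
    r <- condition_table[i, ]
    text <- c(text, sprintf(
      "%s: %d/%d cells responding (%.1f%%) across %d slice(s); amplitude %.1f +/- %.1f %%; onset %.1f +/- %.1f min",
      r$condition, r$n_vdrn, r$n_total_cells, r$pooled_responding_percent,
      r$n_slices, r$amplitude_mean, r$amplitude_sem, r$onset_min_mean,
      r$onset_min_sem))
  }
  if (nrow(comparison_table)) {
    text <- c(text, "", "Comparisons (unpaired two-tailed Welch t test):")
    for (i in seq_len(nrow(comparison_table))) {
      r <- comparison_table[i, ]
      text <- c(text, sprintf("  %s: %s vs %s, t = %.3g, df = %.3g, %s",
                              r$measure, r$group_a, r$group_b, r$t_stat,
                              r$df_welch, format_p(r$p_two_tailed)))
    }
  }
  text <- c(text, "", "Data = mean +/- SEM. No multiple-testing correction applied.")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(condition_table,
                     file.path(out_dir, "condition_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(comparison_table, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    writeLines(text, file.path(out_dir, "report.txt"))
  }
  list(condition_table = condition_table, comparison_table = comparison_table,
       text = text)
}

#' Default whole-study configuration for [run_all()]
#'
#' A deliberately desk-scale study: two imaging conditions with a small
#' number of slices each, plus a mixed set of drug-responsive and
#' rundown-dominated voltage-clamp recordings.
#'
#' @param n_slices slices per imaging condition.
#' @param n_cells cells per slice.
#' @param n_ephys_responders,n_ephys_rundown recording counts.
#' @return nested configuration list.
#' @export
study_config <- function(n_slices = 2L, n_cells = 24L,
                         n_ephys_responders = 2L, n_ephys_rundown = 3L) {
  list(
    imaging = list(
      conditions = c("acsf", "synblock"),
      n_slices = n_slices,
      session = list(n_cells = n_cells, image_height_px = 96L,
                     image_width_px = 128L, baseline_duration_min = 6,
                     post_duration_min = 16)),
    ephys = list(
      n_responders = n_ephys_responders, n_rundown = n_ephys_rundown,
      responder = list(drug_gain = 1.33, rundown_rate = 0.002, noise_sd = 4),
      rundown = list(drug_gain = 1, rundown_rate = 0.012, noise_sd = 4),
      n_baseline_sweeps = 6L, n_post_sweeps = 24L))
}

#' Run the full pipeline: simulate, analyse, report
#'
#' Simulates an imaging study and an ephys study from one master seed,
#' analyses every session, and writes the report bundle plus per-stage CSV
#' outputs and a run log with config hashes. All randomness derives
#' deterministically from `master_seed`, so two runs with the same seed and
#' config produce bit-identical bundles.
#'
#' @param out_dir output directory.
#' @param master_seed integer seed.
#' @param config a [study_config()] list.
#' @param write_stacks also write TIFF stacks per session (default `FALSE`).
#' @return list with `report`, `summaries`, `ephys_table`, invisibly.
#' @export
run_all <- function(out_dir, master_seed = 1L, config = study_config(),
                    write_stacks = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- list()
  calls_tables <- list()
  k <- 0L
  for (cond in config$imaging$conditions) {
    for (s in seq_len(config$imaging$n_slices)) {
      k <- k + 1L
      args <- config$imaging$session
      args$condition_label <- cond
      args$seed <- derive_seed(master_seed, 100L + k)
      cfg <- do.call(imaging_config, args)
      sim <- generate_imaging_session(cfg)
      rois <- rois_from_ground_truth(sim$ground_truth)
      if (write_stacks)
        write_imaging_session(sim$session,
                              file.path(out_dir, sprintf("session_%02d", k)))
      res <- analyze_imaging_session(sim$session, rois)
      summaries[[k]] <- res$summary
      ct <- res$calls
      ct$condition <- cond
      ct$slice <- k
      calls_tables[[k]] <- ct
    }
  }
  calls_all <- do.call(rbind, calls_tables)
  utils::write.csv(calls_all, file.path(out_dir, "responder_calls.csv"),
                   row.names = FALSE)
  slice_table <- do.call(rbind, lapply(summaries, function(s)
    data.frame(condition = s$condition_label, n_total = s$n_total_cells,
               n_vdrn = s$n_vdrn, responding_percent = s$responding_percent,
               qc_pass = s$session_qc_pass)))
  utils::write.csv(slice_table, file.path(out_dir, "slice_summaries.csv"),
                   row.names = FALSE)

  proto <- voltage_protocol()
  ephys_rows <- list()
  n_eph <- config$ephys$n_responders + config$ephys$n_rundown
  for (i in seq_len(n_eph)) {
    kind <- if (i <= config$ephys$n_responders) "responder" else "rundown"
    margs <- config$ephys[[kind]]
    margs$seed <- derive_seed(master_seed, 200L + i)
    model <- do.call(channel_model, margs)
    exp_ <- generate_ephys_experiment(model, proto,
                                      config$ephys$n_baseline_sweeps,
                                      config$ephys$n_post_sweeps)
    dr <- drug_response_timecourse(exp_$sweep_set)
    ephys_rows[[i]] <- data.frame(
      recording = i, planted = kind, classification = dr$classification,
      baseline_peak_pa = dr$baseline_peak, percent_change = dr$percent_change,
      onset_min = dr$onset_min, peak_response_min = dr$peak_response_min)
  }
  ephys_table <- do.call(rbind, ephys_rows)
  utils::write.csv(ephys_table, file.path(out_dir, "ephys_responses.csv"),
                   row.names = FALSE)

  report <- build_report(summaries, out_dir = out_dir)
  log <- list(master_seed = master_seed, config_hash = config_hash(config),
              package_version = as.character(utils::packageVersion("vdrnscreen")))
  writeLines(jsonlite::toJSON(log, auto_unbox = TRUE),
             file.path(out_dir, "run_log.json"))
  invisible(list(report = report, summaries = summaries,
                 ephys_table = ephys_table))
}
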