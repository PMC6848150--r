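# On-disk formats: TIFF stacks + JSON sidecar for imaging sessions,
# long-format CSV + JSON sidecar for sweep sets, run-length CSV for ROI
# masks. Everything round-trips bit-stably for determinism checks.

#' Write an imaging session to a directory
#'
#' Writes `cal.tif` and `txred.tif` (multi-page float TIFF, see
#' [write_tiff_stack()]) plus `session.json` holding stimulation flags,
#' frame times, drug time, condition label and the generator seed if known.
#'
#' @param session an `imaging_session`.
#' @param dir output directory (created if missing).
#' @param write_stacks write the TIFF stacks (default `TRUE`); the sidecar is
#'   always written.
#' @return `dir`, invisibly.
#' @export
write_imaging_session <- function(session, dir, write_stacks = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (write_stacks) {
    write_tiff_stack(session$cal_stack, file.path(dir, "cal.tif"))
    write_tiff_stack(session$txred_stack, file.path(dir, "txred.tif"))
  }
  meta <- list(stim_flags = session$stim_flags, times_s = session$times_s,
               drug_time_s = session$drug_time_s,
               condition_label = session$condition_label,
               seed = session$config$seed %||% NA)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "session.json"))
  invisible(dir)
}

#' Read an imaging session from a directory
#'
#' @param dir directory written by [write_imaging_session()].
#' @return an `imaging_session`.
#' @export
read_imaging_session <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "session.json"))
  structure(list(cal_stack = read_tiff_stack(file.path(dir, "cal.tif")),
                 txred_stack = read_tiff_stack(file.path(dir, "txred.tif")),
                 stim_flags = as.logical(meta$stim_flags),
                 times_s = meta$times_s, drug_time_s = meta$drug_time_s,
                 condition_label = meta$condition_label,
                 config = list(seed = meta$seed)),
            class = "imaging_session")
}

#' Write/read ROI sets as run-length CSV
#'
#' `rois.csv` holds one row per (cell, image row) run:
#' `cell_id,row,col_start,col_end`; `roi_labels.csv` holds
#' `cell_id,txred_positive,in_focus`.
#'
#' @param rois an [roi_set()].
#' @param dir target directory.
#' @return `dir` invisibly (writer); an [roi_set()] (reader).
#' @export
write_roi_set <- function(rois, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  h <- rois$dim[1L]
  runs <- do.call(rbind, lapply(seq_along(rois$masks), function(i) {
    idx <- sort(rois$masks[[i]])
    r <- ((idx - 1L) %% h) + 1L
    cc <- ((idx - 1L) %/% h) + 1L
    do.call(rbind, lapply(sort(unique(r)), function(rv) {
      cols <- sort(cc[r == rv])
      breaks <- c(0L, which(diff(cols) != 1L), length(cols))
      data.frame(cell_id = i, row = rv,
                 col_start = cols[breaks[-length(breaks)] + 1L],
                 col_end = cols[breaks[-1L]])
    }))
  }))
  runs <- runs[order(runs$cell_id, runs$row, runs$col_start), ]
  utils::write.csv(runs, file.path(dir, "rois.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cell_id = seq_along(rois$masks),
                              txred_positive = rois$txred_positive,
                              in_focus = rois$in_focus,
                              height = rois$dim[1L], width = rois$dim[2L]),
                   file.path(dir, "roi_labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(dir) {
  runs <- utils::read.csv(file.path(dir, "rois.csv"))
  labels <- utils::read.csv(file.path(dir, "roi_labels.csv"))
  h <- labels$height[1L]; w <- labels$width[1L]
  masks <- lapply(labels$cell_id, function(i) {
    rr <- runs[runs$cell_id == i, ]
    unlist(lapply(seq_len(nrow(rr)), function(j)
      (rr$col_start[j]:rr$col_end[j] - 1L) * h + rr$row[j]))
  })
  roi_set(masks, c(h, w), labels$txred_positive, labels$in_focus)
}

#' Write a sweep set as long-format CSV plus protocol sidecar
#'
#' `sweeps.csv`: `sweep_id,time_ms,v_mv,current`; `pn_sweeps.csv`: same for
#' the P/N sub-sweeps at the sub-step voltage; `protocol.json`: protocol
#' fields, sweep start times and drug time.
#'
#' @param sweep_set a `sweep_set`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_sweep_set <- function(sweep_set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- do.call(rbind, lapply(seq_along(sweep_set$sweeps), function(k)
    data.frame(sweep_id = k, time_ms = sweep_set$sweeps[[k]]$time_ms,
               v_mv = sweep_set$step_mv[k],
               current = sweep_set$sweeps[[k]]$current)))
  utils::write.csv(long, file.path(dir, "sweeps.csv"), row.names = FALSE)
  pn <- do.call(rbind, lapply(seq_along(sweep_set$pn_sweeps), function(k)
    data.frame(sweep_id = k, time_ms = sweep_set$pn_sweeps[[k]]$time_ms,
               v_mv = sweep_set$protocol$pn_step_mv[2L],
               current = sweep_set$pn_sweeps[[k]]$current)))
  utils::write.csv(pn, file.path(dir, "pn_sweeps.csv"), row.names = FALSE)
  meta <- c(unclass(sweep_set$protocol),
            list(start_times_s = sweep_set$start_times_s,
                 step_mv = sweep_set$step_mv,
                 drug_time_s = sweep_set$drug_time_s))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "protocol.json"))
  invisible(dir)
}

#' Read a sweep set written by [write_sweep_set()]
#'
#' @param dir directory containing `sweeps.csv`, `pn_sweeps.csv`,
#'   `protocol.json`.
#' @return a `sweep_set`.
#' @export
read_sweep_set <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "protocol.json"))
  proto <- voltage_protocol(holding_mv = meta$holding_mv,
                            step_levels_mv = meta$step_levels_mv,
                            step_duration_ms = meta$step_duration_ms,
                            pre_ms = meta$pre_ms, post_ms = meta$post_ms,
                            inter_sweep_interval_s = meta$inter_sweep_interval_s,
                            pn_n_reps = meta$pn_n_reps,
                            pn_step_mv = meta$pn_step_mv,
                            sampling_khz = meta$sampling_khz)
  long <- utils::read.csv(file.path(dir, "sweeps.csv"))
  pn <- utils::read.csv(file.path(dir, "pn_sweeps.csv"))
  by_id <- function(d) {
    lapply(sort(unique(d$sweep_id)), function(k) {
      s <- d[d$sweep_id == k, ]
      data.frame(time_ms = s$time_ms, current = s$current)
    })
  }
  sweeps <- by_id(long)
  pn_sweeps <- by_id(pn)
  structure(list(sweeps = sweeps, step_mv = meta$step_mv,
                 start_times_s = meta$start_times_s, protocol = proto,
                 pn_sweeps = pn_sweeps, drug_time_s = meta$drug_time_s),
            class = "sweep_set")
}
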