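# Synthetic stimulus-locked two-channel imaging sessions with ground truth.
#
# Emulated structure: frames alternate unstimulated/stimulated at 0.1 Hz
# (stimulation at 0.05 Hz); somata are circular Gaussian intensity profiles
# on a smooth (planar) background; a minority responder subpopulation gains
# stimulated-frame fluorescence after drug onset with a logistic ramp; the
# counterstain channel is static except for configured z-drift events.

#' Imaging-session generator configuration
#'
#' Defaults describe the screening conditions the pipeline is designed for:
#' 10-s frame interval (0.1 Hz imaging, 0.05 Hz stimulation), a >=5 min
#' pre-drug baseline, a ~7% responder subpopulation with percent-change
#' amplitudes centred on 24% (SD 14, clipped to [10, 66.5]) and post-drug
#' onsets centred on 6.7 min (SD 3.6, clipped to [2, 15] min), and pixel
#' noise calibrated so that three baseline SDs correspond to roughly a 7%
#' delta-F/F change for a typical cell.
#'
#' @param image_height_px,image_width_px frame size in pixels.
#' @param n_cells number of somata to plant.
#' @param cell_radius_px ROI disk radius in pixels.
#' @param txred_positive_fraction fraction of counterstain-positive cells.
#' @param responder_fraction fraction of cells that are planted responders
#'   (must not exceed `1 - txred_positive_fraction`; responders are always
#'   counterstain-negative).
#' @param responder_amplitude_mean,responder_amplitude_sd percent-change
#'   amplitude distribution (clipped to `amplitude_range`).
#' @param amplitude_range clip range for planted amplitudes, percent.
#' @param responder_onset_mean_min,responder_onset_sd_min onset distribution
#'   in minutes after drug application (clipped to `onset_range_min`).
#' @param onset_range_min clip range for planted onsets, minutes.
#' @param onset_rise_s 10-90% rise time of the logistic onset ramp, seconds.
#' @param baseline_dff_mean,baseline_dff_sd per-cell resting stimulus-evoked
#'   delta-F/F distribution (clipped below at 0.08).
#' @param cell_f1_mean,cell_f1_sd per-cell resting fluorescence amplitude
#'   above background (arbitrary camera units, clipped below at 30).
#' @param background_level planar background intensity scale.
#' @param photobleach_rate fractional intensity loss per frame.
#' @param noise_sd per-pixel Gaussian noise SD, camera units.
#' @param frame_interval_s seconds between frames (default 10).
#' @param baseline_duration_min,post_duration_min epoch durations, minutes.
#' @param drug_time_min drug application time (default: end of baseline).
#' @param z_drift_events list of `c(frame, magnitude)` pairs; from `frame`
#'   onward the counterstain channel is blurred and attenuated by `magnitude`
#'   in `[0, 1]`.
#' @param condition_label free-text condition tag.
#' @param seed integer RNG seed; identical config and seed give bit-identical
#'   sessions.
#' @return object of class `imaging_config`.
#' @export
imaging_config <- function(image_height_px = 120L, image_width_px = 160L,
                           n_cells = 40L, cell_radius_px = 5,
                           txred_positive_fraction = 0.15,
                           responder_fraction = 0.073,
                           responder_amplitude_mean = 24,
                           responder_amplitude_sd = 14,
                           amplitude_range = c(10, 66.5),
                           responder_onset_mean_min = 6.7,
                           responder_onset_sd_min = 3.6,
                           onset_range_min = c(2, 15),
                           onset_rise_s = 60,
                           baseline_dff_mean = 0.25, baseline_dff_sd = 0.05,
                           cell_f1_mean = 100, cell_f1_sd = 20,
                           background_level = 20,
                           photobleach_rate = 2e-4, noise_sd = 4.5,
                           frame_interval_s = 10,
                           baseline_duration_min = 10,
                           post_duration_min = 25,
                           drug_time_min = NULL,
                           z_drift_events = list(),
                           condition_label = "synblock", seed = 1L) {
  check_fraction(txred_positive_fraction, "txred_positive_fraction")
  check_fraction(responder_fraction, "responder_fraction")
  stop_if(responder_fraction > 1 - txred_positive_fraction + 1e-12,
          paste0("responder_fraction (%g) exceeds the counterstain-negative ",
                 "fraction (%g): responders must be TxRed-negative"),
          responder_fraction, 1 - txred_positive_fraction)
  check_positive(frame_interval_s, "frame_interval_s")
  check_positive(baseline_duration_min, "baseline_duration_min")
  check_positive(post_duration_min, "post_duration_min")
  for (nm in c("responder_amplitude_sd", "responder_onset_sd_min",
               "baseline_dff_sd", "cell_f1_sd", "noise_sd"))
    check_positive(get(nm), nm, strict = FALSE)
  stop_if(photobleach_rate < 0 || photobleach_rate >= 1,
          "photobleach_rate must be in [0, 1)")
  stop_if(n_cells < 1L, "n_cells must be >= 1")
  drug_time_min <- drug_time_min %||% baseline_duration_min
  stop_if(drug_time_min > baseline_duration_min,
          "drug_time_min must not exceed baseline_duration_min")
  cfg <- as.list(environment())
  cfg$nm <- NULL
  structure(cfg, class = "imaging_config")
}

# Logistic onset ramp in [0, 1]; scale set by the 10-90% rise time.
onset_ramp <- function(t_s, onset_s, rise_s) {
  s <- rise_s / (2 * log(9))
  1 / (1 + exp(-(t_s - onset_s) / s))
}

clipnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Plant cell positions, labels and response parameters
#'
#' Draws the ground truth for a session without rendering any frames: cell
#' centers on a jittered non-overlapping grid, exactly
#' `round(txred_positive_fraction * n_cells)` counterstain-positive cells and
#' exactly `round(responder_fraction * n_cells)` responders (always
#' counterstain-negative), per-cell resting fluorescence, baseline delta-F/F,
#' amplitudes and onsets. Per-cell draws are consumed in cell-index order
#' under one seeded stream, so ground truth is reproducible on any platform.
#'
#' @param config an [imaging_config()].
#' @return object of class `imaging_ground_truth`: a list with `cells`
#'   (data frame: `center_row`, `center_col`, `radius_px`, `txred_positive`,
#'   `responder`, `planted_f1`, `planted_baseline_dff`, `planted_amplitude`,
#'   `planted_onset_s`) and `drug_time_s`.
#' @export
plant_imaging_ground_truth <- function(config) {
  stop_if(!inherits(config, "imaging_config"), "`config` must be an imaging_config")
  c_ <- config
  with_seed(c_$seed, {
    pitch <- 2 * c_$cell_radius_px + 4
    margin <- c_$cell_radius_px + 2
    rows <- seq(margin + 1, c_$image_height_px - margin, by = pitch)
    cols <- seq(margin + 1, c_$image_width_px - margin, by = pitch)
    n_slots <- length(rows) * length(cols)
    stop_if(n_slots < c_$n_cells,
            "n_cells (%d) exceeds the non-overlapping capacity (%d) of a %d x %d field",
            c_$n_cells, n_slots, c_$image_height_px, c_$image_width_px)
    slots <- sample.int(n_slots, c_$n_cells)
    center_row <- rows[(slots - 1L) %% length(rows) + 1L] +
      stats::runif(c_$n_cells, -1, 1)
    center_col <- cols[(slots - 1L) %/% length(rows) + 1L] +
      stats::runif(c_$n_cells, -1, 1)

    n_tx <- round(c_$txred_positive_fraction * c_$n_cells)
    n_resp <- round(c_$responder_fraction * c_$n_cells)
    txred_positive <- logical(c_$n_cells)
    txred_positive[sample.int(c_$n_cells, n_tx)] <- TRUE
    responder <- logical(c_$n_cells)
    neg <- which(!txred_positive)
    stop_if(n_resp > length(neg),
            "cannot place %d responders among %d TxRed-negative cells",
            n_resp, length(neg))
    responder[neg[sample.int(length(neg), n_resp)]] <- TRUE

    f1_amp <- clipnorm(c_$n_cells, c_$cell_f1_mean, c_$cell_f1_sd, lo = 30)
    baseline_dff <- clipnorm(c_$n_cells, c_$baseline_dff_mean,
                             c_$baseline_dff_sd, lo = 0.08)
    drug_time_s <- c_$drug_time_min * 60
    amplitude <- rep(NA_real_, c_$n_cells)
    onset_s <- rep(NA_real_, c_$n_cells)
    idx <- which(responder)
    amplitude[idx] <- clipnorm(length(idx), c_$responder_amplitude_mean,
                               c_$responder_amplitude_sd,
                               c_$amplitude_range[1L], c_$amplitude_range[2L])
    onset_s[idx] <- drug_time_s + 60 * clipnorm(
      length(idx), c_$responder_onset_mean_min, c_$responder_onset_sd_min,
      c_$onset_range_min[1L], c_$onset_range_min[2L])

    cells <- data.frame(center_row = center_row, center_col = center_col,
                        radius_px = c_$cell_radius_px,
                        txred_positive = txred_positive, responder = responder,
                        planted_f1 = NA_real_, cell_amplitude = f1_amp,
                        planted_baseline_dff = baseline_dff,
                        planted_amplitude = amplitude,
                        planted_onset_s = onset_s)
    structure(list(cells = cells, drug_time_s = drug_time_s, config = c_),
              class = "imaging_ground_truth")
  })
}

# Per-cell rendering profile: Gaussian restricted to the ROI disk and
# normalised so its mean over the disk is exactly 1. Returns linear indices
# and weights.
cell_profile <- function(center_row, center_col, radius, h, w) {
  r0 <- max(1L, floor(center_row - radius)); r1 <- min(h, ceiling(center_row + radius))
  c0 <- max(1L, floor(center_col - radius)); c1 <- min(w, ceiling(center_col + radius))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - center_row)^2, (cc - center_col)^2, "+")
  keep <- d2 <= radius^2
  sigma <- radius / 2
  val <- exp(-d2[keep] / (2 * sigma^2))
  val <- val / mean(val)
  idx <- (rep(cc, each = length(rr))[keep] - 1L) * h + rep(rr, length(cc))[keep]
  list(idx = idx, val = val)
}

# Separable Gaussian blur with replicated edges (small sigma).
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(2.5 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(img); w <- ncol(img)
  blur_rows <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- pmin(pmax(seq_len(nrow(m)) + off, 1L), nrow(m))
      out <- out + k[j] * m[src, , drop = FALSE]
    }
    out
  }
  t(blur_rows(t(blur_rows(img))))
}

#' Generate a two-channel imaging session with ground truth
#'
#' Renders the indicator-channel stack (alternating resting F1 and stimulated
#' F2 frames with photobleach decay and pixel noise) and the static
#' counterstain stack (with configured z-drift events applied as a blur plus
#' attenuation). Responder cells' stimulated-frame gain ramps logistically
#' from the planted baseline delta-F/F to `baseline * (1 + amplitude/100)`
#' around the planted onset.
#'
#' @param config an [imaging_config()].
#' @return list with `session` (class `imaging_session`: `cal_stack`,
#'   `txred_stack`, `stim_flags`, `times_s`, `drug_time_s`,
#'   `condition_label`, `config`) and `ground_truth`
#'   (class `imaging_ground_truth`, with `planted_f1` filled in as the exact
#'   noise-free mean intensity over each cell's ROI disk in frame 1).
#' @export
generate_imaging_session <- function(config) {
  gt <- plant_imaging_ground_truth(config)
  c_ <- config
  h <- c_$image_height_px; w <- c_$image_width_px
  n_frames <- 2L * floor((c_$baseline_duration_min + c_$post_duration_min) *
                           60 / (2 * c_$frame_interval_s))
  times_s <- (seq_len(n_frames) - 1) * c_$frame_interval_s
  stim_flags <- rep(c(FALSE, TRUE), n_frames %/% 2L)

  cells <- gt$cells
  profiles <- lapply(seq_len(nrow(cells)), function(i)
    cell_profile(cells$center_row[i], cells$center_col[i],
                 cells$radius_px[i], h, w))

  # planar background: removed exactly by rolling-ball subtraction
  bg <- c_$background_level *
    (1 + 0.2 * (col(matrix(0, h, w)) / w) + 0.1 * (row(matrix(0, h, w)) / h))
  bg_vec <- as.vector(bg)

  base_vec <- bg_vec
  for (i in seq_len(nrow(cells)))
    base_vec[profiles[[i]]$idx] <- base_vec[profiles[[i]]$idx] +
      cells$cell_amplitude[i] * profiles[[i]]$val
  cells$planted_f1 <- vapply(seq_len(nrow(cells)), function(i) {
    p <- profiles[[i]]
    mean(bg_vec[p$idx]) + cells$cell_amplitude[i]
  }, numeric(1))
  gt$cells <- cells

  # counterstain base image: positive somata plus crisp filamentous processes
  tx_struct <- with_seed(derive_seed(c_$seed, 1L), {
    tx <- matrix(c_$background_level / 2, h, w)
    for (i in which(cells$txred_positive)) {
      p <- profiles[[i]]
      tx[p$idx] <- tx[p$idx] + 80 * p$val
    }
    for (s in seq_len(12L)) {
      r0 <- stats::runif(1, 5, h - 5); c0 <- stats::runif(1, 5, w - 5)
      ang <- stats::runif(1, 0, pi); len <- stats::runif(1, 10, 30)
      steps <- seq(0, len, by = 0.5)
      rr <- pmin(pmax(round(r0 + steps * sin(ang)), 1L), h)
      cc <- pmin(pmax(round(c0 + steps * cos(ang)), 1L), w)
      tx[cbind(rr, cc)] <- tx[cbind(rr, cc)] + 60
    }
    tx
  })

  # z-drift: persistent blur + attenuation of the counterstain from the event
  # frame onward (the indicator channel is not the drift monitor)
  drift_state <- function(frame_idx) {
    m <- 0
    for (ev in c_$z_drift_events) if (frame_idx >= ev[1L]) m <- max(m, ev[2L])
    m
  }
  drift_cache <- list()
  tx_for_frame <- function(frame_idx) {
    m <- drift_state(frame_idx)
    if (m <= 0) return(tx_struct)
    key <- sprintf("%.6f", m)
    if (is.null(drift_cache[[key]])) {
      drift_cache[[key]] <<- (1 - m) * tx_struct +
        m * (0.7 * gaussian_blur(tx_struct, 1 + 2 * m))
    }
    drift_cache[[key]]
  }

  dff_at <- function(t) {
    d <- cells$planted_baseline_dff
    r <- which(cells$responder)
    d[r] <- d[r] * (1 + cells$planted_amplitude[r] / 100 *
                      onset_ramp(t, cells$planted_onset_s[r], c_$onset_rise_s))
    d
  }

  cal <- array(0, c(h, w, n_frames))
  txs <- array(0, c(h, w, n_frames))
  with_seed(derive_seed(c_$seed, 2L), {
    for (f in seq_len(n_frames)) {
      bleach <- (1 - c_$photobleach_rate)^(f - 1L)
      v <- base_vec
      if (stim_flags[f]) {
        d <- dff_at(times_s[f])
        for (i in seq_len(nrow(cells))) {
          p <- profiles[[i]]
          v[p$idx] <- v[p$idx] + cells$cell_amplitude[i] * d[i] * p$val
        }
      }
      frame <- bleach * v
      if (c_$noise_sd > 0) frame <- frame + stats::rnorm(h * w, 0, c_$noise_sd)
      cal[, , f] <- pmax(matrix(frame, h, w), 0)
      txf <- tx_for_frame(f)
      if (c_$noise_sd > 0) txf <- txf +
          matrix(stats::rnorm(h * w, 0, c_$noise_sd), h, w)
      txs[, , f] <- pmax(txf, 0)
    }
  })

  session <- structure(list(cal_stack = cal, txred_stack = txs,
                            stim_flags = stim_flags, times_s = times_s,
                            drug_time_s = gt$drug_time_s,
                            condition_label = c_$condition_label,
                            config = c_),
                       class = "imaging_session")
  list(session = session, ground_truth = gt)
}

#' ROI set from generator ground truth
#'
#' Builds the per-cell disk masks the generator planted, labelled with the
#' counterstain ground truth. This stands in for the manual somatic ROI
#' drawing done on real acquisitions.
#'
#' @param ground_truth an [imaging_ground_truth][plant_imaging_ground_truth()].
#' @return an [roi_set()].
#' @export
rois_from_ground_truth <- function(ground_truth) {
  c_ <- ground_truth$config
  h <- c_$image_height_px; w <- c_$image_width_px
  cells <- ground_truth$cells
  masks <- lapply(seq_len(nrow(cells)), function(i)
    cell_profile(cells$center_row[i], cells$center_col[i],
                 cells$radius_px[i], h, w)$idx)
  roi_set(masks, c(h, w), cells$txred_positive)
}
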