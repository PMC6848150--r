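# Translational (XY) image stabilisation via FFT cross-correlation.

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Wrap circular index k (0-based) into a signed shift for axis length n.
wrap_shift <- function(k, n) ifelse(k > n / 2, k - n, k)

# 1-D parabolic sub-sample refinement around a peak with neighbours ym, y0, yp.
parabolic_offset <- function(ym, y0, yp) {
  den <- ym + yp - 2 * y0
  if (!is.finite(den) || den == 0) return(0)
  off <- 0.5 * (ym - yp) / den
  max(min(off, 0.5), -0.5)
}

# Shift an image by (dr, dc) pixels using bilinear interpolation with
# replicated edges. Positive dr moves content down, positive dc right.
shift_image <- function(img, dr, dc) {
  h <- nrow(img); w <- ncol(img)
  r_src <- seq_len(h) - dr
  c_src <- seq_len(w) - dc
  r0 <- pmin(pmax(floor(r_src), 1L), h); r1 <- pmin(r0 + 1L, h)
  c0 <- pmin(pmax(floor(c_src), 1L), w); c1 <- pmin(c0 + 1L, w)
  fr <- pmin(pmax(r_src - r0, 0), 1); fc <- pmin(pmax(c_src - c0, 0), 1)
  a <- img[r0, c0, drop = FALSE] * (1 - fr) + img[r1, c0, drop = FALSE] * fr
  b <- img[r0, c1, drop = FALSE] * (1 - fr) + img[r1, c1, drop = FALSE] * fr
  a * matrix(1 - fc, h, w, byrow = TRUE) + b * matrix(fc, h, w, byrow = TRUE)
}

#' Estimate and correct per-frame translation of a stack
#'
#' Estimates, for every frame, the 2-D translation relative to a reference
#' frame by the peak of the circular cross-correlation (computed on
#' mean-subtracted frames via FFT), refined to sub-pixel precision by
#' parabolic interpolation of the correlation peak. Frames are then resampled
#' by the inverse shift (bilinear, replicated edges).
#'
#' Frames with zero variance (e.g. all-zero dropouts) have no defined shift:
#' they are flagged, reported as `NA`, and left uncorrected.
#'
#' @param stack numeric array, height x width x frames.
#' @param reference_frame_index index of the reference frame (default 1).
#' @return list with `shifts` (frames x 2 matrix, (row, col) pixels),
#'   `corrected` (stack resampled by the inverse shifts) and `flagged`
#'   (logical, per frame).
#' @export
register_translation <- function(stack, reference_frame_index = 1L) {
  stop_if(!is.array(stack) || length(dim(stack)) != 3L,
          "`stack` must be an H x W x T array")
  nt <- dim(stack)[3L]
  stop_if(nt < 2L, "registration needs at least 2 frames")
  stop_if(reference_frame_index < 1L || reference_frame_index > nt,
          "reference_frame_index out of range")
  h <- dim(stack)[1L]; w <- dim(stack)[2L]
  ref <- stack[, , reference_frame_index]
  stop_if(stats::sd(ref) == 0, "reference frame has zero variance")
  fref <- Conj(fft2(ref - mean(ref)))

  shifts <- matrix(NA_real_, nt, 2L, dimnames = list(NULL, c("row", "col")))
  flagged <- logical(nt)
  corrected <- stack
  for (t in seq_len(nt)) {
    frame <- stack[, , t]
    if (stats::sd(frame) == 0) {
      flagged[t] <- TRUE
      next
    }
    cc <- Re(ifft2(fft2(frame - mean(frame)) * fref))
    pk <- arrayInd(which.max(cc), dim(cc))
    pr <- pk[1L]; pc <- pk[2L]
    idx <- function(i, n) ((i - 1L) %% n) + 1L
    dr_sub <- parabolic_offset(cc[idx(pr - 1L, h), pc], cc[pr, pc], cc[idx(pr + 1L, h), pc])
    dc_sub <- parabolic_offset(cc[pr, idx(pc - 1L, w)], cc[pr, pc], cc[pr, idx(pc + 1L, w)])
    dr <- wrap_shift(pr - 1L, h) + dr_sub
    dc <- wrap_shift(pc - 1L, w) + dc_sub
    shifts[t, ] <- c(dr, dc)
    if (dr != 0 || dc != 0) corrected[, , t] <- shift_image(frame, -dr, -dc)
  }
  list(shifts = shifts, corrected = corrected, flagged = flagged)
}
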