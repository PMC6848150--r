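# Rolling-ball background subtraction.
#
# The background of a frame is its grayscale opening with a ball structuring
# element: the upper envelope of a sphere of the given pixel radius rolled
# beneath the intensity surface. Subtracting it removes smooth shading while
# preserving compact bright features (somata) that the ball cannot enter.

# Ball structuring element: integer offsets and sphere heights.
make_ball_se <- function(radius_px) {
  r <- radius_px
  dr <- rep(-floor(r):floor(r), each = 2L * floor(r) + 1L)
  dc <- rep(-floor(r):floor(r), times = 2L * floor(r) + 1L)
  keep <- dr^2 + dc^2 <= r^2
  list(dr = dr[keep], dc = dc[keep],
       z = sqrt(r^2 - dr[keep]^2 - dc[keep]^2))
}

# Grayscale erosion/dilation with a structuring function, vectorised over
# SE offsets. Out-of-image samples are ignored (equivalent to +/-Inf padding).
morph_ball <- function(img, se, op = c("erode", "dilate")) {
  op <- match.arg(op)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(if (op == "erode") Inf else -Inf, h, w)
  for (k in seq_along(se$dr)) {
    dr <- se$dr[k]; dc <- se$dc[k]; z <- se$z[k]
    r_dst <- max(1L, 1L - dr):min(h, h - dr)
    c_dst <- max(1L, 1L - dc):min(w, w - dc)
    src <- img[r_dst + dr, c_dst + dc, drop = FALSE]
    if (op == "erode") {
      out[r_dst, c_dst] <- pmin(out[r_dst, c_dst], src - z)
    } else {
      out[r_dst, c_dst] <- pmax(out[r_dst, c_dst], src + z)
    }
  }
  out
}

# Block-minimum downsample by integer factor s (edge blocks replicate).
block_min <- function(img, s) {
  h <- nrow(img); w <- ncol(img)
  hp <- ceiling(h / s) * s; wp <- ceiling(w / s) * s
  if (hp > h) img <- rbind(img, img[rep(h, hp - h), , drop = FALSE])
  if (wp > w) img <- cbind(img, img[, rep(w, wp - w), drop = FALSE])
  rows <- Reduce(pmin, lapply(seq_len(s), function(k)
    img[seq(k, hp, by = s), , drop = FALSE]))
  Reduce(pmin, lapply(seq_len(s), function(k)
    rows[, seq(k, wp, by = s), drop = FALSE]))
}

# Bilinear upsample of a block-downsampled image back to h x w, treating
# small-image pixels as block centers.
resize_bilinear <- function(small, h, w, s) {
  interp_mat <- function(n_out, n_in) {
    pos <- pmin(pmax(((seq_len(n_out) - 0.5) / s) + 0.5, 1), n_in)
    lo <- pmin(floor(pos), n_in - if (n_in > 1L) 1L else 0L)
    frac <- pos - lo
    m <- matrix(0, n_out, n_in)
    m[cbind(seq_len(n_out), lo)] <- 1 - frac
    if (n_in > 1L) m[cbind(seq_len(n_out), pmin(lo + 1L, n_in))] <-
      m[cbind(seq_len(n_out), pmin(lo + 1L, n_in))] + frac
    m
  }
  interp_mat(h, nrow(small)) %*% small %*% t(interp_mat(w, ncol(small)))
}

#' Rolling-ball background estimate
#'
#' @param image 2-D nonnegative numeric matrix.
#' @param radius_px ball radius in pixels (default 50).
#' @param method `"exact"` computes the grayscale opening at full resolution;
#'   `"fast"` estimates it on a block-minimum downsampled image (ImageJ-style)
#'   and bilinearly upsamples, which is accurate for backgrounds much smoother
#'   than the ball; `"auto"` picks `"fast"` when the radius warrants shrinking.
#' @param shrink integer downsample factor for `"fast"` (chosen from the
#'   radius when `NULL`).
#' @return matrix of background estimates, pointwise in `[0, image]`.
#' @export
rolling_ball_background <- function(image, radius_px = 50,
                                    method = c("auto", "exact", "fast"),
                                    shrink = NULL) {
  method <- match.arg(method)
  stop_if(!is.matrix(image) || !is.numeric(image), "`image` must be a numeric matrix")
  check_positive(radius_px, "radius_px")
  stop_if(radius_px >= min(dim(image)),
          "radius_px (%g) must be smaller than the image extent (%d x %d)",
          radius_px, nrow(image), ncol(image))
  if (is.null(shrink)) {
    shrink <- if (radius_px >= 30) 8L else if (radius_px >= 15) 4L else if (radius_px >= 8) 2L else 1L
  }
  if (method == "auto") method <- if (shrink > 1L) "fast" else "exact"
  if (method == "exact" || shrink <= 1L) {
    se <- make_ball_se(radius_px)
    bg <- morph_ball(morph_ball(image, se, "erode"), se, "dilate")
  } else {
    small <- block_min(image, shrink)
    se <- make_ball_se(max(radius_px / shrink, 1))
    bg_small <- morph_ball(morph_ball(small, se, "erode"), se, "dilate")
    bg <- resize_bilinear(bg_small, nrow(image), ncol(image), shrink)
  }
  pmin(bg, image)
}

#' Subtract the rolling-ball background from an image
#'
#' Returns `image - rolling_ball_background(image, ...)`, which is nonnegative
#' for nonnegative input because the opening is anti-extensive.
#'
#' @inheritParams rolling_ball_background
#' @return background-subtracted matrix (same shape, all values >= 0).
#' @export
subtract_background_rolling_ball <- function(image, radius_px = 50,
                                             method = c("auto", "exact", "fast"),
                                             shrink = NULL) {
  pmax(image - rolling_ball_background(image, radius_px, method, shrink), 0)
}
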