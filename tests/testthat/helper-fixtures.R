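# Shared fixtures, all generated in code.

# Small smooth test image: tilted plane plus Gaussian spots.
spot_image <- function(h = 40, w = 50, n_spots = 5, amp = 80, seed = 1) {
  set.seed(seed)
  img <- outer(seq_len(h), seq_len(w), function(r, c) 10 + 0.05 * r + 0.02 * c)
  for (i in seq_len(n_spots)) {
    r0 <- runif(1, 8, h - 8); c0 <- runif(1, 8, w - 8)
    img <- img + amp * exp(-(outer((seq_len(h) - r0)^2,
                                   (seq_len(w) - c0)^2, "+")) / (2 * 2^2))
  }
  img
}

# Brute-force grayscale rolling-ball oracle: pixelwise erosion then dilation
# with the sphere-height structuring function, independent of the package's
# shifted-matrix implementation.
oracle_rolling_ball <- function(img, radius) {
  h <- nrow(img); w <- ncol(img)
  r <- floor(radius)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  z <- sqrt(radius^2 - off$dr^2 - off$dc^2)
  pad <- function(m, fill) {
    p <- matrix(fill, h + 2 * r, w + 2 * r)
    p[(r + 1):(r + h), (r + 1):(r + w)] <- m
    p
  }
  hp <- h + 2 * r
  lin_off <- off$dc * hp + off$dr
  run <- function(m, fill, f, sgn) {
    p <- pad(m, fill)
    centers <- as.vector(outer((r + 1):(r + h),
                               (((r + 1):(r + w)) - 1) * hp, "+"))
    out <- vapply(centers, function(ctr) f(p[ctr + lin_off] + sgn * z),
                  numeric(1))
    matrix(out, h, w)
  }
  ero <- run(img, Inf, min, -1)
  run(ero, -Inf, max, +1)
}

# Tiny imaging config for fast tests; dots override the small defaults.
quick_config <- function(...) {
  args <- utils::modifyList(
    list(baseline_duration_min = 6, post_duration_min = 8, n_cells = 12L,
         image_height_px = 64L, image_width_px = 80L),
    list(...))
  do.call(imaging_config, args)
}
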