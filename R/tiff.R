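# Minimal baseline TIFF I/O for multi-page grayscale stacks.
#
# Scope is deliberately narrow: little-endian, uncompressed, single-sample
# grayscale, 32-bit IEEE float (written) plus 8/16-bit unsigned and 32/64-bit
# float (read). That covers the stacks this package writes and the common
# export formats of scientific cameras after conversion. No R TIFF package is
# assumed to be available.

TIFF_TAG <- list(width = 256L, length = 257L, bits = 258L, compression = 259L,
                 photometric = 262L, strip_offsets = 273L, spp = 277L,
                 rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L)

#' Write a frame stack as a multi-page TIFF
#'
#' Writes an `H x W x T` numeric array as an uncompressed little-endian
#' grayscale TIFF with one page per frame, 32-bit float samples, row-major
#' pixel order.
#'
#' @param stack numeric array with dimensions height x width x frames, or a
#'   matrix (single frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_tiff_stack()]
#' @export
write_tiff_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  stop_if(!is.array(stack) || length(dim(stack)) != 3L,
          "`stack` must be an H x W x T array")
  h <- dim(stack)[1L]; w <- dim(stack)[2L]; nt <- dim(stack)[3L]
  data_bytes <- h * w * 4L
  n_tags <- length(TIFF_TAG)
  ifd_bytes <- 2L + 12L * n_tags + 4L
  page_bytes <- ifd_bytes + data_bytes

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(8L, con, size = 4L, endian = "little")

  tag_entry <- function(id, type, count, value) {
    # type 3 = SHORT, 4 = LONG; value fits in the 4-byte field
    c(writeBin(id, con, size = 2L, endian = "little"),
      writeBin(type, con, size = 2L, endian = "little"),
      writeBin(count, con, size = 4L, endian = "little"))
    if (type == 3L) {
      writeBin(value, con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(value, con, size = 4L, endian = "little")
    }
    invisible(NULL)
  }

  for (t in seq_len(nt)) {
    ifd_off <- 8L + (t - 1L) * page_bytes
    data_off <- ifd_off + ifd_bytes
    next_off <- if (t < nt) ifd_off + page_bytes else 0L
    writeBin(n_tags, con, size = 2L, endian = "little")
    tag_entry(TIFF_TAG$width, 4L, 1L, as.integer(w))
    tag_entry(TIFF_TAG$length, 4L, 1L, as.integer(h))
    tag_entry(TIFF_TAG$bits, 3L, 1L, 32L)
    tag_entry(TIFF_TAG$compression, 3L, 1L, 1L)
    tag_entry(TIFF_TAG$photometric, 3L, 1L, 1L)
    tag_entry(TIFF_TAG$strip_offsets, 4L, 1L, as.integer(data_off))
    tag_entry(TIFF_TAG$spp, 3L, 1L, 1L)
    tag_entry(TIFF_TAG$rows_per_strip, 4L, 1L, as.integer(h))
    tag_entry(TIFF_TAG$strip_bytes, 4L, 1L, as.integer(data_bytes))
    tag_entry(TIFF_TAG$sample_format, 3L, 1L, 3L)
    writeBin(as.integer(next_off), con, size = 4L, endian = "little")
    # row-major: transpose so rows are contiguous
    writeBin(as.numeric(t(stack[, , t])), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF into a frame stack
#'
#' Supports uncompressed little- or big-endian grayscale TIFFs with 8- or
#' 16-bit unsigned or 32/64-bit float samples, one sample per pixel, any strip
#' layout.
#'
#' @param path TIFF file path.
#' @return numeric array, height x width x frames.
#' @export
read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  endian <- if (rawToChar(raw[1:2]) == "II") "little" else "big"
  magic <- readBin(raw[3:4], "integer", size = 2L, endian = endian)
  stop_if(magic != 42L, "not a TIFF file: %s", path)
  u <- function(off, size, n = 1L) {
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = size >= 4L, endian = endian)
  }
  ifd_off <- u(4L, 4L)
  frames <- list()
  while (ifd_off != 0L) {
    n_tags <- u(ifd_off, 2L)
    tags <- list()
    for (i in seq_len(n_tags)) {
      e <- ifd_off + 2L + (i - 1L) * 12L
      id <- u(e, 2L); type <- u(e + 2L, 2L); count <- u(e + 4L, 4L)
      val_size <- c(1L, 1L, 2L, 4L)[match(type, c(1L, 2L, 3L, 4L))]
      if (is.na(val_size)) next
      total <- val_size * count
      voff <- if (total <= 4L) e + 8L else u(e + 8L, 4L)
      tags[[as.character(id)]] <- u(voff, val_size, count)
    }
    g <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    w <- g(TIFF_TAG$width); h <- g(TIFF_TAG$length)
    bits <- g(TIFF_TAG$bits, 1L)[1L]
    comp <- g(TIFF_TAG$compression, 1L)
    fmt <- g(TIFF_TAG$sample_format, 1L)[1L]
    spp <- g(TIFF_TAG$spp, 1L)
    stop_if(comp != 1L, "only uncompressed TIFF is supported")
    stop_if(spp != 1L, "only single-sample grayscale TIFF is supported")
    offs <- g(TIFF_TAG$strip_offsets)
    cnts <- g(TIFF_TAG$strip_bytes)
    bytes <- unlist(lapply(seq_along(offs), function(i) {
      raw[(offs[i] + 1L):(offs[i] + cnts[i])]
    }))
    px <- if (fmt == 3L && bits %in% c(32L, 64L)) {
      readBin(bytes, "double", n = h * w, size = bits %/% 8L, endian = endian)
    } else if (fmt %in% c(1L, 4L) && bits == 8L) {
      as.numeric(readBin(bytes, "integer", n = h * w, size = 1L,
                         signed = FALSE, endian = endian))
    } else if (fmt %in% c(1L, 4L) && bits == 16L) {
      as.numeric(readBin(bytes, "integer", n = h * w, size = 2L,
                         signed = FALSE, endian = endian))
    } else {
      stop_if(TRUE, "unsupported TIFF sample layout (bits=%d, format=%d)",
              bits, fmt)
    }
    frames[[length(frames) + 1L]] <- t(matrix(px, nrow = w, ncol = h))
    ifd_off <- u(ifd_off + 2L + n_tags * 12L, 4L)
  }
  h <- nrow(frames[[1L]]); w <- ncol(frames[[1L]])
  array(unlist(frames), c(h, w, length(frames)))
}
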