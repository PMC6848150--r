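# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_if <- function(cond, msg, ...) {
  if (isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv) else if (exists(".Random.seed", envir = genv, inherits = FALSE)) rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation; result always a valid 32-bit seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + k * 10007) %% 2147483647)
}

# Start index of the first run of >= m consecutive TRUE, or NA.
first_run_start <- function(x, m) {
  x[is.na(x)] <- FALSE
  if (!length(x)) return(NA_integer_)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values & r$lengths >= m)
  if (!length(i)) NA_integer_ else starts[i[1L]]
}

check_fraction <- function(x, name) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1,
          "`%s` must be a single value in [0, 1]", name)
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  bad <- !is.numeric(x) || length(x) != 1L || is.na(x) ||
    (if (strict) x <= 0 else x < 0)
  stop_if(bad, "`%s` must be %s", name, if (strict) "> 0" else ">= 0")
  invisible(x)
}

# Stable md5 fingerprint of an R list (via canonical JSON on a temp file).
config_hash <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(js, tf)
  unname(tools::md5sum(tf))
}

# Centered boxcar mean with shrinking windows at the edges.
boxcar <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (k - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
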