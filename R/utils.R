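# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. All stochastic generators go through
# this so results are bit-reproducible given (spec, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# Contiguous runs of TRUE in a logical vector: tibble of start/end indices
# (inclusive). Zero-row tibble when no TRUE present.
true_runs <- function(x) {
  x <- as.logical(x)
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Centered boxcar smoothing; edge samples keep their raw values. Used by
# feature extractors that read extrema off noisy sweeps, where the raw
# pointwise minimum/maximum is biased by the extreme-value statistics of
# the noise.
smooth_boxcar <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1L) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

stop_sociodyn <- function(...) stop(..., call. = FALSE)
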