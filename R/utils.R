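# Internal helpers: reproducible substreams and filtering primitives.

# Deterministic 32-bit sub-seed from a master seed plus string/numeric tags.
# Lehmer-style mixing; factors kept small enough that products stay exact in
# double precision (< 2^53).
substream_seed <- function(seed, ...) {
  tag <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 17
  for (ch in utf8ToInt(tag)) {
    h <- (h * 69069 + ch) %% 2147483629
  }
  as.integer(h)
}

# Evaluate expr with a locally-set RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Zero-phase Butterworth band-pass of a single numeric vector.
band_filter_vector <- function(x, sampling_rate, low, high, order = 4) {
  ny <- sampling_rate / 2
  stopifnot(low > 0, low < high, high < ny)
  bf <- signal::butter(order, c(low, high) / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mt <- function(...) stop(sprintf(...), call. = FALSE)
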