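# Internal helpers: classed error conditions, millisecond/sample conversion,
# and counter-based RNG substreams.

stop_eegaffect <- function(class, msg, ...) {
  extra <- list(...)
  cond <- structure(
    class = c(class, "eegaffect_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), extra)
  )
  stop(cond)
}

invalid_argument <- function(msg, ...) stop_eegaffect("invalid_argument", msg, ...)

#' Convert a duration in milliseconds to a sample count
#'
#' @param ms Duration in milliseconds.
#' @param rate Sampling rate in Hz.
#' @return Integer number of samples (rounded to nearest).
#' @keywords internal
ms_to_samples <- function(ms, rate) {
  if (any(ms < 0) || rate <= 0) invalid_argument("durations and rate must be positive")
  as.integer(round(ms * rate / 1000))
}

# FNV-1a string hash folded into [0, 2^31 - 2]; used to derive independent,
# order-free RNG substreams from one root seed and a set of string keys.
hash_key <- function(key) {
  bytes <- utf8ToInt(key)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% (2^31 - 1))
}

#' Derive a deterministic substream seed from a root seed and keys
#'
#' Subject-, clip- and column-level randomness is drawn from substreams so
#' simulated units are independent of the order in which they are generated.
#'
#' @param seed Root integer seed.
#' @param ... Character or numeric keys identifying the substream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  as.integer((hash_key(key) + abs(as.numeric(seed))) %% (2^31 - 1))
}

# Evaluate expr under a local RNG state seeded from a substream.
with_substream <- function(seed, ..., expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, ...))
  expr
}

clamp <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)
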