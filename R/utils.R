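# Internal helpers: seeded RNG streams and small numeric utilities.

#' Derive a child seed from a parent seed and a stream offset
#'
#' One global integer seed is fanned out to per-stage / per-stream seeds by a
#' fixed multiplicative mix so that independent stages draw from independent,
#' reproducible streams. The result always fits in a 32-bit signed integer.
#'
#' @param seed parent integer seed.
#' @param offset non-negative integer identifying the stream.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(offset))
  # 2^31 - 1 is prime-free but fine as a modulus for stream separation
  as.integer((abs(seed) * 7919 + offset * 104729 + 17) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Stable non-cryptographic string hash (FNV-1a over UTF-8 bytes), reduced to
# a positive integer < 2^31 - 1. Used to key per-token RNG streams.
hash_string <- function(x) {
  vapply(x, function(s) {
    b <- utf8ToInt(enc2utf8(s))
    h <- 2166136261
    for (v in b) {
      h <- bitwXor(as.integer(h %% 2147483647), as.integer(v))
      h <- (h * 16777619) %% 2147483647
    }
    as.integer(h %% 2147483646L + 1L)
  }, integer(1), USE.NAMES = FALSE)
}

l2norm <- function(x) sqrt(sum(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
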