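# Internal helpers shared across modules.

#' Derive a reproducible substream seed from a root seed
#'
#' Each randomised output draws from its own substream so that adding a new
#' output to a generator never perturbs the streams of existing outputs.
#' The substream seed is a deterministic 31-bit hash of (root seed, index).
#'
#' @param seed integer root seed.
#' @param index nonnegative integer substream counter.
#' @return an integer in [0, 2^31 - 1] suitable for [set.seed()].
#' @keywords internal
substream_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  s <- (abs(as.double(seed)) %% m)
  # two rounds of a Lehmer-style mix keep distinct (seed, index) pairs apart
  s <- (s * 48271 + index * 1009 + 1) %% m
  s <- (s * 16807 + 12345) %% m
  as.integer(s)
}

#' Run code under a temporary RNG state
#'
#' Sets the RNG to a substream of `seed` for the duration of `expr`, then
#' restores the caller's RNG state, so generator internals never leak into
#' user sessions.
#' @keywords internal
with_substream <- function(seed, index, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, index))
  force(expr)
}

# stop() with sprintf formatting; call. = FALSE keeps messages user-facing
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# scalar checks used by config validators
is_count1 <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}
is_frac1 <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}
is_pos1 <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
}
is_nonneg1 <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0
}
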