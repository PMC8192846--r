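#' Derive a reproducible sub-stream seed
#'
#' All randomness in famrank flows from a single integer master seed.  Each
#' consumer (a feature family in the simulator, a resample in a round, a
#' stage of the pipeline) draws from its own sub-stream whose seed is a
#' deterministic hash of the master seed and a path of tags.  Adding a new
#' consumer therefore never perturbs the draws of existing ones.
#'
#' The hash is a plain polynomial-rolling scheme over the tag path, mixed
#' with the master seed modulo 2^31 - 1; all arithmetic stays below 2^53 so
#' the computation is exact in double precision and identical on every
#' platform.
#'
#' @param seed Integer master seed.
#' @param ... Tags (character or integer-ish scalars) naming the sub-stream,
#'   e.g. `substream_seed(1, "round", 3, "resample", 57)`.
#' @return A single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' substream_seed(1, "ka_ks")
#' substream_seed(1, "round", 2) != substream_seed(1, "round", 3)
#' @export
substream_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, prime
  tag <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 0
  if (nzchar(tag)) {
    for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% m
  }
  mixed <- (h * 69069 + (abs(seed) %% m) * 50021 + 17) %% (m - 1)
  as.integer(mixed + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_substream <- function(seed, expr) {
  withr::with_seed(seed, expr)
}
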