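# Reproducible, decoupled random streams.
#
# Each stream owns a private copy of R's Mersenne-Twister state so that the
# sequencer and the agent consume independent randomness derived from one
# master seed: adding draws to one stream never perturbs the other.

#' Derive a deterministic sub-seed from a master seed
#'
#' Mixes a master seed with a stream index through a Lehmer-style integer
#' recurrence, staying below 2^31 so the result is a valid R integer seed.
#'
#' @param master_seed integer master seed.
#' @param stream_id non-negative integer identifying the sub-stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, stream_id) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.numeric(stream_id), length(stream_id) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  s <- (abs(master_seed) %% (m - 1)) + 1
  for (i in 1:3) {
    s <- (s * 48271 + (stream_id %% m) * 7919 + i) %% m
  }
  as.integer(if (s == 0) 1 else s)
}

#' Create an independent random stream
#'
#' @param seed integer seed for this stream.
#' @return an environment of class `wcst_rng` holding the stream state.
#' @export
new_rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$seed <- as.integer(seed)
  e$state <- NULL
  class(e) <- "wcst_rng"
  e
}

# Evaluate `expr` (a function of no arguments) under the stream's RNG state,
# saving the advanced state back into the stream and restoring the caller's
# global RNG afterwards.
with_stream <- function(stream, f) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  if (is.null(stream$state)) set.seed(stream$seed) else
    assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", old, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
  })
  f()
}

stream_runif <- function(stream, n = 1L) with_stream(stream, function() runif(n))

stream_sample <- function(stream, x, size = 1L) {
  with_stream(stream, function() x[sample.int(length(x), size)])
}
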