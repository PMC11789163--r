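# Reproducible independent RNG streams on top of base R's generator.
# Each stream owns a saved .Random.seed; evaluating code under a stream
# swaps it in and captures the advanced state afterwards, leaving the
# global state untouched.  Replica-exchange runs give every bath its own
# stream so that disabling exchange reproduces independent chains
# bit-exactly.

#' Create an independent RNG stream
#'
#' @param seed Integer seed.
#' @return An environment of class `rng_stream` holding the stream state.
#' @export
rng_stream <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  st <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  e <- new.env(parent = emptyenv())
  e$state <- st
  class(e) <- "rng_stream"
  e
}

#' Evaluate a function under an RNG stream
#'
#' @param stream An [rng_stream()].
#' @param fn A zero-argument function.
#' @return The value of `fn()`; the stream state is advanced.
#' @export
with_stream <- function(stream, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream$state, globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  fn()
}

# Derive a child seed from a stream (keeps child seeds < 2^31).
.spawn_seed <- function(stream) {
  with_stream(stream, function() as.integer(floor(runif(1) * 2147483646)) + 1L)
}
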