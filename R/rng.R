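#' Seeded, named random-number substreams
#'
#' A session is driven by one master seed; every stochastic component
#' (daily food placement, pirate spawning, pirate eating, each policy) draws
#' from its own named substream so that, e.g., swapping agent policies never
#' perturbs the environment's randomness. Substream seeds are derived
#' deterministically from the master seed and the stream name.
#'
#' @param master integer master seed.
#' @param name character stream name (e.g. `"food"`, `"pirate_eat"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' substream_seed(42, "food")
#' @export
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 31 + cp) %% 2147483647
  as.integer((abs(as.numeric(master)) + h) %% 2147483647)
}

#' Create an independent RNG stream
#'
#' Wraps an R RNG state in an environment so draws can be made without
#' touching (or being affected by) the global `.Random.seed`.
#'
#' @param seed integer seed for the stream.
#' @return An object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "rng_stream"
  e
}

#' Draw from an RNG stream
#'
#' Evaluates `fn(...)` with the stream's RNG state installed, then captures
#' the advanced state back into the stream. The global RNG state is restored
#' on exit.
#'
#' @param stream an [rng_stream()].
#' @param fn a function that consumes random numbers (e.g. `runif`).
#' @param ... arguments passed on to `fn`.
#' @return The value of `fn(...)`.
#' @export
stream_draw <- function(stream, fn, ...) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  res <- fn(...)
  stream$state <- get(".Random.seed", envir = globalenv())
  res
}
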