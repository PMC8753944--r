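#' Independent random-number substreams
#'
#' The simulator draws every stochastic quantity (interarrival times, patient
#' types, new/old status, each station's service time) from its own named
#' substream, all derived deterministically from a single replication seed.
#' Keeping sources on separate streams supports common random numbers: two
#' runs that differ only in staffing consume identical arrival and service
#' draws, which sharpens paired comparisons between candidate schedules.
#'
#' A stream is an environment holding a saved `.Random.seed` state; drawing
#' from a stream swaps that state in, runs the sampler, and saves the state
#' back, so streams never interfere with each other or with the caller's RNG.
#'
#' @param seed integer master seed (one replication).
#' @param names character vector of stream names.
#' @return named list of stream objects.
#' @keywords internal
rng_substreams <- function(seed, names) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(names) >= 1L)
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(names))
  streams <- lapply(sub_seeds, function(s) {
    set.seed(s)
    e <- new.env(parent = emptyenv())
    e$state <- get(".Random.seed", envir = globalenv())
    e
  })
  names(streams) <- names
  streams
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Evaluate a sampler under a stream's RNG state
#'
#' @param stream a stream created by [rng_substreams()].
#' @param fn a zero-argument function performing the draws.
#' @return the value of `fn()`.
#' @keywords internal
stream_eval <- function(stream, fn) {
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  assign(".Random.seed", stream$state, envir = globalenv())
  out <- fn()
  stream$state <- get(".Random.seed", envir = globalenv())
  out
}
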