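#' Independent random-number substreams
#'
#' A single master seed is expanded into named substreams so that each
#' source of randomness in a simulation (training/test data, weight
#' initialisation, the feedback vector, weight-perturbation proposals,
#' surrogate noise) draws from its own stream.  Changing the learning
#' rule therefore never perturbs the data stream, which makes paired
#' comparisons across rules possible.
#'
#' A stream is a mutable object holding its own `.Random.seed` state;
#' [stream_eval()] temporarily installs that state, evaluates a drawing
#' function, and saves the advanced state back, leaving the global RNG
#' untouched.
#'
#' @param seed integer master seed (kept below 2^31).
#' @return `rng_stream()` returns an object of class `rng_stream`;
#'   `rule_streams()` returns a named list of five streams.
#' @keywords internal
#' @name rng-streams
NULL

.stream_ids <- c(data = 1L, init = 2L, feedback = 3L, wp = 4L, surrogate = 5L)

#' @rdname rng-streams
#' @param stream name of the substream, one of
#'   `"data"`, `"init"`, `"feedback"`, `"wp"`, `"surrogate"`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  id <- .stream_ids[[match.arg(stream, names(.stream_ids))]]
  # mix master seed and stream id; modulus keeps the result a valid R integer
  as.integer((abs(as.double(seed)) * 1009 + id * 7919) %% 2147483629)
}

#' @rdname rng-streams
#' @export
rng_stream <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(env) <- "rng_stream"
  env
}

#' Evaluate a drawing function under a stream's RNG state
#'
#' @param stream an [rng_stream()] object.
#' @param fn a function performing random draws.
#' @param ... arguments passed on to `fn`.
#' @return the value of `fn(...)`.
#' @keywords internal
#' @export
stream_eval <- function(stream, fn, ...) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  fn(...)
}

#' @rdname rng-streams
#' @export
rule_streams <- function(seed) {
  streams <- lapply(names(.stream_ids), function(nm) {
    rng_stream(derive_seed(seed, nm))
  })
  names(streams) <- names(.stream_ids)
  streams
}
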