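#' Perturbed activation-derivative surrogates
#'
#' In the middle-layer update the derivative `f'` of the activation
#' need not be computed exactly: a biological circuit may only have a
#' shifted, rescaled, smoothed or noisy estimate of it.  A surrogate
#' replaces the step function `f'orig = ReLU'` in the update (the
#' forward pass and the output-layer update are untouched):
#'
#' * `exact` — the true derivative of the configured activation.
#' * `y_shift` — `step(I) + param` (vertical shift).
#' * `x_shift` — `step(I - param)` (threshold shift).
#' * `y_scale` — `param * step(I)`.
#' * `sigmoid_slope` — `1 / (1 + exp(-param * I))`, a smooth step with
#'   slope constant `param`; approaches the step as `param -> Inf`.
#' * `noise_unfixed` — `step(I)` plus fresh Gaussian noise of sd
#'   `param` per element per evaluation.
#' * `noise_fixed` — `step(I)` plus a per-neuron Gaussian offset of sd
#'   `param`, drawn once at construction and reused every epoch.
#'
#' All perturbed kinds are defined relative to the ReLU step; only
#' `exact` is meaningful for tanh networks.
#'
#' @param kind surrogate kind, see Details.
#' @param param shift amount, scale constant, slope constant or noise
#'   standard deviation, depending on `kind`.
#' @param m number of middle-layer neurons (required for
#'   `noise_fixed`).
#' @param stream an [rng_stream()] (required for `noise_fixed`).
#' @return an object of class `fprime_surrogate`.
#' @examples
#' st <- rng_stream(1)
#' s <- make_surrogate("sigmoid_slope", param = 50)
#' eval_surrogate(s, matrix(c(-0.1, 0.1), 1), "relu")
#' @export
make_surrogate <- function(kind = c("exact", "y_shift", "x_shift", "y_scale",
                                    "sigmoid_slope", "noise_unfixed",
                                    "noise_fixed"),
                           param = 0, m = NULL, stream = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(param) || length(param) != 1L || !is.finite(param)) {
    stop("`param` must be a finite number", call. = FALSE)
  }
  fixed_noise <- NULL
  if (kind == "noise_fixed") {
    if (is.null(m) || as.integer(m) < 1L) {
      stop("`m` is required for kind = \"noise_fixed\"", call. = FALSE)
    }
    fixed_noise <- stream_eval(stream, stats::rnorm, as.integer(m), sd = param)
  }
  structure(
    list(kind = kind, param = as.double(param), fixed_noise = fixed_noise),
    class = "fprime_surrogate"
  )
}

#' Evaluate a derivative surrogate on middle-layer currents
#'
#' @param s a [make_surrogate()] object.
#' @param I `n x m` matrix of middle-layer input currents.
#' @param activation activation name; perturbed kinds require
#'   `"relu"`.
#' @param stream an [rng_stream()] (required for `noise_unfixed`).
#' @return `n x m` matrix of surrogate derivative values.
#' @export
eval_surrogate <- function(s, I, activation = "relu", stream = NULL) {
  stopifnot(inherits(s, "fprime_surrogate"))
  I <- as.matrix(I)
  if (s$kind == "exact") {
    return(activation_deriv(activation, I))
  }
  if (activation != "relu") {
    stop("perturbed surrogate kinds are defined for the relu step only",
         call. = FALSE)
  }
  step <- (I > 0) * 1
  switch(s$kind,
    y_shift = step + s$param,
    x_shift = (I - s$param > 0) * 1,
    y_scale = s$param * step,
    sigmoid_slope = 1 / (1 + exp(-s$param * I)),
    noise_unfixed = step + stream_eval(stream, function() {
      matrix(stats::rnorm(length(I), sd = s$param), nrow(I), ncol(I))
    }),
    noise_fixed = {
      if (length(s$fixed_noise) != ncol(I)) {
        stop("noise_fixed surrogate was built for a different m", call. = FALSE)
      }
      sweep(step, 2L, s$fixed_noise, "+")
    }
  )
}

#' @export
print.fprime_surrogate <- function(x, ...) {
  cat(sprintf("f' surrogate: kind = %s, param = %g\n", x$kind, x$param))
  invisible(x)
}
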