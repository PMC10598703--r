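#' Initialise a three-layer rate network
#'
#' The network has `d` input units, `m` hidden (middle-layer) units with
#' a tanh or ReLU activation and per-neuron bias, and a single linear
#' output unit with a scalar bias:
#' `I = X W1' + b1`, `h = f(I)`, `yhat = h W2 + b2`.
#'
#' Middle-layer weights and biases are drawn i.i.d. uniform on
#' `[-hidden_half_width, +hidden_half_width]`, by default fan-in scaled
#' (`1/sqrt(d + 1)`, counting the bias input) so that input currents are
#' of order one regardless of the input dimension — the standard choice
#' for random hidden layers.  Output weights and bias are drawn uniform
#' on `[-half_width, +half_width]` (default 0.01), so the network's
#' initial output is near zero and the initial test MSE on a `{-1, +1}`
#' target is close to 1.
#'
#' @param d input dimension.
#' @param m number of middle-layer neurons.
#' @param activation `"tanh"` or `"relu"`.
#' @param half_width half-width of the output-layer initialisation
#'   interval (default 0.01).
#' @param stream an [rng_stream()].
#' @param hidden_half_width half-width for the middle-layer weights and
#'   biases; `NULL` (default) means fan-in scaling `1/sqrt(d + 1)`.
#' @return An object of class `network_params`: list with `W1` (`m x d`
#'   middle-layer weights), `b1` (length-`m` middle-layer biases), `W2`
#'   (length-`m` output weights), `b2` (scalar output bias),
#'   `activation`, `d`, `m`.
#' @export
init_params <- function(d, m, activation = c("tanh", "relu"),
                        half_width = 0.01, stream,
                        hidden_half_width = NULL) {
  activation <- match.arg(activation)
  d <- as.integer(d)
  m <- as.integer(m)
  if (any(is.na(c(d, m))) || d < 1L || m < 1L) {
    stop("`d` and `m` must be positive integers", call. = FALSE)
  }
  if (!is.numeric(half_width) || length(half_width) != 1L ||
      !is.finite(half_width) || half_width <= 0) {
    stop("`half_width` must be a positive number", call. = FALSE)
  }
  if (is.null(hidden_half_width)) hidden_half_width <- 1 / sqrt(d + 1)
  if (!is.numeric(hidden_half_width) || hidden_half_width <= 0) {
    stop("`hidden_half_width` must be a positive number", call. = FALSE)
  }
  stream_eval(stream, function() {
    structure(
      list(
        W1 = matrix(stats::runif(m * d, -hidden_half_width, hidden_half_width), m, d),
        b1 = stats::runif(m, -hidden_half_width, hidden_half_width),
        W2 = stats::runif(m, -half_width, half_width),
        b2 = stats::runif(1, -half_width, half_width),
        activation = activation, d = d, m = m
      ),
      class = "network_params"
    )
  })
}

#' Assemble network parameters from explicit components
#'
#' Mainly for tests and worked examples where exact weights are needed.
#'
#' @param W1 `m x d` matrix.
#' @param W2 length-`m` vector.
#' @param activation `"tanh"` or `"relu"`.
#' @param b1 length-`m` middle-layer biases (default all zero).
#' @param b2 scalar output bias (default zero).
#' @return a `network_params` object.
#' @export
network_params <- function(W1, W2, activation = c("tanh", "relu"),
                           b1 = NULL, b2 = 0) {
  activation <- match.arg(activation)
  W1 <- as.matrix(W1)
  W2 <- as.double(W2)
  if (length(W2) != nrow(W1)) {
    stop("length(W2) must equal nrow(W1)", call. = FALSE)
  }
  if (is.null(b1)) b1 <- rep(0, nrow(W1))
  structure(
    list(W1 = W1, b1 = as.double(b1), W2 = W2, b2 = as.double(b2),
         activation = activation, d = ncol(W1), m = nrow(W1)),
    class = "network_params"
  )
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf(
    "three-layer network: %d -> %d (%s) -> 1 (linear), |W1| <= %.3g, |W2| <= %.3g\n",
    x$d, x$m, x$activation, max(abs(x$W1)), max(abs(x$W2))
  ))
  invisible(x)
}

#' Activation functions and their exact derivatives
#'
#' ReLU: `f(s) = max(s, 0)` with derivative the step function and the
#' tie-break `f'(0) := 0`.  tanh: `f(s) = tanh(s)` with derivative
#' `1 - tanh(s)^2`.
#'
#' @param name `"tanh"` or `"relu"`.
#' @param s numeric scalar, vector or matrix.
#' @return numeric of the same shape as `s`.
#' @export
activation_value <- function(name, s) {
  switch(match.arg(name, c("tanh", "relu")),
    tanh = tanh(s),
    relu = pmax(s, 0)
  )
}

#' @rdname activation_value
#' @export
activation_deriv <- function(name, s) {
  switch(match.arg(name, c("tanh", "relu")),
    tanh = 1 - tanh(s)^2,
    relu = (s > 0) * 1
  )
}

#' Forward pass through the network
#'
#' Computes, for a batch of inputs, the middle-layer input currents
#' `I = X W1' + b1`, the middle-layer activities `h = f(I)`, the linear
#' output `yhat = h W2 + b2`, and the errors `e = y - yhat`.
#'
#' @param params a [init_params()] object.
#' @param X `n x d` input matrix.
#' @param y length-`n` target vector.
#' @return An object of class `forward_state`: list with `I`, `h`
#'   (`n x m` matrices), `yhat`, `e` (length-`n` vectors).
#' @export
forward <- function(params, X, y) {
  stopifnot(inherits(params, "network_params"))
  X <- as.matrix(X)
  if (ncol(X) != params$d) {
    stop(sprintf("X has %d columns, network expects %d", ncol(X), params$d),
         call. = FALSE)
  }
  if (length(y) != nrow(X)) {
    stop("length(y) must equal nrow(X)", call. = FALSE)
  }
  I <- sweep(X %*% t(params$W1), 2L, params$b1, "+")
  h <- activation_value(params$activation, I)
  yhat <- drop(h %*% params$W2) + params$b2
  structure(
    list(I = I, h = h, yhat = yhat, e = as.double(y) - yhat),
    class = "forward_state"
  )
}

#' Test-set mean squared error
#'
#' The "predicted squared error": the mean over a held-out dataset of
#' `(y - yhat)^2`.  This is the learning-curve metric used throughout.
#'
#' @param params a [init_params()] object.
#' @param dataset a [kdxor_dataset()] (or any list with `X`, `y`).
#' @return a non-negative scalar.
#' @export
test_mse <- function(params, dataset) {
  if (is.null(dataset$X) || nrow(as.matrix(dataset$X)) == 0L) {
    stop("dataset must be non-empty", call. = FALSE)
  }
  mean(forward(params, dataset$X, dataset$y)$e^2)
}

# batch cost J = 0.5 * sum of squared errors, the quantity whose exact
# gradient BP follows and which WP's accept/reject decision evaluates
batch_cost <- function(params, X, y) {
  0.5 * sum(forward(params, X, y)$e^2)
}
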