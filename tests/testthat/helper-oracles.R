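# Independent oracles used across test files.

# central finite-difference gradient of the batch cost J = 0.5 * sum(e^2)
# with respect to every trainable parameter of the network
fd_gradient <- function(params, X, y, eps = 1e-6) {
  grad_of <- function(get, set) {
    v0 <- get(params)
    g <- numeric(length(v0))
    for (i in seq_along(v0)) {
      vp <- v0; vp[i] <- vp[i] + eps
      vm <- v0; vm[i] <- vm[i] - eps
      g[i] <- (triadnet:::batch_cost(set(params, vp), X, y) -
               triadnet:::batch_cost(set(params, vm), X, y)) / (2 * eps)
    }
    g
  }
  list(
    W1 = matrix(grad_of(function(p) as.vector(p$W1),
                        function(p, v) { p$W1 <- matrix(v, nrow(p$W1)); p }),
                nrow(params$W1)),
    b1 = grad_of(function(p) p$b1, function(p, v) { p$b1 <- v; p }),
    W2 = grad_of(function(p) p$W2, function(p, v) { p$W2 <- v; p }),
    b2 = grad_of(function(p) p$b2, function(p, v) { p$b2 <- v; p })
  )
}

# explicit per-sample, per-neuron double-loop forward pass
forward_loop_oracle <- function(params, X, y) {
  n <- nrow(X); m <- params$m
  I <- matrix(0, n, m); h <- matrix(0, n, m)
  yhat <- numeric(n)
  for (s in seq_len(n)) {
    for (j in seq_len(m)) {
      acc <- params$b1[j]
      for (i in seq_len(params$d)) acc <- acc + params$W1[j, i] * X[s, i]
      I[s, j] <- acc
      h[s, j] <- activation_value(params$activation, acc)
      yhat[s] <- yhat[s] + params$W2[j] * h[s, j]
    }
    yhat[s] <- yhat[s] + params$b2
  }
  list(I = I, h = h, yhat = yhat, e = y - yhat)
}

# small random network + batch for oracle comparisons
random_instance <- function(seed, n = 6, d = 4, m = 5,
                            activation = "tanh", scale = 0.5) {
  st <- rng_stream(seed)
  stream_eval(st, function() {
    p <- network_params(
      W1 = matrix(stats::runif(m * d, -scale, scale), m, d),
      W2 = stats::runif(m, -scale, scale),
      activation = activation,
      b1 = stats::runif(m, -scale, scale),
      b2 = stats::runif(1, -scale, scale)
    )
    X <- matrix(stats::runif(n * d, -1, 1), n, d)
    y <- stats::runif(n, -1, 1)
    list(params = p, X = X, y = y)
  })
}
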