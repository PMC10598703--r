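#' Specify a k-dXOR task
#'
#' The k-dXOR task is a regression task with `d` real inputs of which
#' only the first `k` are relevant: the target is the product of the
#' signs of the first `k` coordinates, `y = sign(x1) * ... * sign(xk)`,
#' so `y` is always +1 or -1.  The remaining `d - k` coordinates are
#' noise inputs that carry no information about the target.  Each input
#' coordinate is drawn as a fair +/-1 sign plus small Gaussian jitter of
#' standard deviation `sigma`.
#'
#' The task emulates a laboratory reward-prediction experiment in which
#' the animal must learn an expected reward amount from a stimulus; with
#' `k = 2` it is a continuous embedding of reversal learning (a cue
#' input flips the meaning of the other relevant input).
#'
#' @param d total input dimension.
#' @param k relevant input dimension, `1 <= k <= d`.
#' @param sigma standard deviation of the per-coordinate Gaussian
#'   jitter; default 0.01.
#' @return An object of class `kdxor_spec` with fields `d`, `k`,
#'   `sigma` and the derived noise dimension `d_noise = d - k`.
#' @examples
#' spec <- kdxor_spec(d = 12, k = 2)
#' spec$d_noise
#' @export
kdxor_spec <- function(d, k = 2L, sigma = 0.01) {
  d <- as.integer(d)
  k <- as.integer(k)
  if (length(d) != 1L || is.na(d) || d < 1L) {
    stop("`d` must be a positive integer", call. = FALSE)
  }
  if (length(k) != 1L || is.na(k) || k < 1L || k > d) {
    stop("`k` must satisfy 1 <= k <= d", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop("`sigma` must be a non-negative number", call. = FALSE)
  }
  structure(
    list(d = d, k = k, sigma = as.double(sigma), d_noise = d - k),
    class = "kdxor_spec"
  )
}

#' @export
print.kdxor_spec <- function(x, ...) {
  cat(sprintf(
    "k-dXOR task: d = %d inputs (%d relevant, %d noise), jitter sigma = %g\n",
    x$d, x$k, x$d_noise, x$sigma
  ))
  invisible(x)
}

# sign with the fixed convention sign(0) := +1 (a measure-zero event for
# the jittered generator, but the labelling must be deterministic)
sign_pos <- function(x) ifelse(x >= 0, 1, -1)

#' Sample k-dXOR input coordinates
#'
#' Every entry is drawn independently as `m + eps` where `m` is +1 or -1
#' with probability 1/2 each and `eps` is Gaussian with mean 0 and
#' standard deviation `spec$sigma`.
#'
#' @param n number of samples (rows).
#' @param spec a [kdxor_spec()].
#' @param stream an [rng_stream()] supplying the randomness.
#' @return an `n x d` numeric matrix.
#' @export
sample_inputs <- function(n, spec, stream) {
  stopifnot(inherits(spec, "kdxor_spec"))
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  d <- spec$d
  sigma <- spec$sigma
  stream_eval(stream, function() {
    means <- (stats::runif(n * d) > 0.5) * 2 - 1
    jitter <- if (sigma > 0) stats::rnorm(n * d) * sigma else 0
    matrix(means + jitter, nrow = n, ncol = d)
  })
}

#' Label k-dXOR inputs
#'
#' `y_i` is the product over the first `k` columns of the sign of
#' `X[i, j]`, with `sign(0) := +1`.
#'
#' @param X an `n x d` input matrix.
#' @param k relevant input dimension, `k <= ncol(X)`.
#' @return a length-`n` vector with entries in `{-1, +1}`.
#' @export
kdxor_label <- function(X, k) {
  X <- as.matrix(X)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > ncol(X)) {
    stop("`k` must satisfy 1 <= k <= ncol(X)", call. = FALSE)
  }
  y <- rep(1, nrow(X))
  for (j in seq_len(k)) {
    y <- y * sign_pos(X[, j])
  }
  y
}

#' Generate a k-dXOR dataset
#'
#' Inputs are drawn first and the target is then computed from their
#' signs; training and test sets come from the same distribution.
#'
#' @inheritParams sample_inputs
#' @return An object of class `kdxor_dataset`: a list with fields `X`
#'   (`n x d` matrix), `y` (length-`n` vector in `{-1, +1}`) and `spec`.
#' @examples
#' st <- rng_stream(1)
#' ds <- kdxor_dataset(8, kdxor_spec(d = 12, k = 2), st)
#' table(ds$y)
#' @export
kdxor_dataset <- function(n, spec, stream) {
  X <- sample_inputs(n, spec, stream)
  structure(
    list(X = X, y = kdxor_label(X, spec$k), spec = spec),
    class = "kdxor_dataset"
  )
}

#' @export
print.kdxor_dataset <- function(x, ...) {
  cat(sprintf(
    "k-dXOR dataset: %d samples, d = %d (k = %d), P(y = +1) = %.3f\n",
    nrow(x$X), x$spec$d, x$spec$k, mean(x$y > 0)
  ))
  invisible(x)
}

#' Write / read a k-dXOR dataset as CSV
#'
#' Columns are `x1 .. xd` followed by `y`.
#'
#' @param dataset a [kdxor_dataset()].
#' @param path file path.
#' @return `write_kdxor_csv` returns `path` invisibly;
#'   `read_kdxor_csv` returns a list with fields `X` and `y`.
#' @export
write_kdxor_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "kdxor_dataset"))
  df <- as.data.frame(dataset$X)
  names(df) <- paste0("x", seq_len(ncol(dataset$X)))
  df$y <- dataset$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kdxor_csv
#' @export
read_kdxor_csv <- function(path) {
  df <- utils::read.csv(path)
  ycol <- match("y", names(df))
  list(X = as.matrix(df[, -ycol, drop = FALSE]), y = df[[ycol]])
}
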