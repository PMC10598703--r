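#' Training configuration
#'
#' Bundles every setting of a single simulated learning run: the task
#' geometry, the network, the rule, the derivative surrogate and the
#' protocol constants.  One epoch is one weight update computed from a
#' fresh batch of `batch_size` training trials, so the total number of
#' training samples consumed is `epochs * batch_size`.  The learning
#' rate is fixed across epochs (no scheduling).
#'
#' The default learning rate depends on the activation: 0.02 for tanh,
#' 0.01 for ReLU — chosen large enough to maximise training speed while
#' remaining stable.
#'
#' @param d,k,sigma task geometry, see [kdxor_spec()].
#' @param m number of middle-layer neurons.
#' @param rule learning-rule name, see [rule_config()].
#' @param activation `"tanh"` or `"relu"`.
#' @param eta learning rate; `NULL` picks the activation default.
#' @param wp_epsilon weight-perturbation proposal sd.
#' @param surrogate list with `kind` and `param`, see
#'   [make_surrogate()].
#' @param batch_size training trials per epoch (default 8).
#' @param epochs number of weight updates (default 1000).
#' @param test_n size of the held-out test set, drawn once per run
#'   (default 1000).
#' @param threshold success threshold on the test MSE (default 0.1).
#' @param init_half_width weight-initialisation half-width.
#' @param seed master seed for the run.
#' @return an object of class `train_config`.
#' @export
train_config <- function(d = 12, k = 2, sigma = 0.01, m = 20, rule = "bp",
                         activation = c("relu", "tanh"), eta = NULL,
                         wp_epsilon = 0.005,
                         surrogate = list(kind = "exact", param = 0),
                         batch_size = 8, epochs = 1000, test_n = 1000,
                         threshold = 0.1, init_half_width = 0.01, seed = 1) {
  activation <- match.arg(activation)
  if (is.null(eta)) eta <- if (activation == "tanh") 0.02 else 0.01
  if (as.integer(batch_size) < 1L || as.integer(epochs) < 1L ||
      as.integer(test_n) < 1L) {
    stop("`batch_size`, `epochs` and `test_n` must be positive integers",
         call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("`threshold` must be positive", call. = FALSE)
  }
  structure(
    list(
      task = kdxor_spec(d, k, sigma),
      m = as.integer(m),
      rule = rule_config(rule, eta, wp_epsilon),
      activation = activation,
      surrogate = surrogate,
      batch_size = as.integer(batch_size),
      epochs = as.integer(epochs),
      test_n = as.integer(test_n),
      threshold = as.double(threshold),
      init_half_width = as.double(init_half_width),
      seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

#' @export
print.train_config <- function(x, ...) {
  cat(sprintf(
    "train config: rule = %s, %d-%d-1 %s net, eta = %g, batch %d, %d epochs, seed %d\n",
    x$rule$rule, x$task$d, x$m, x$activation, x$rule$eta,
    x$batch_size, x$epochs, x$seed
  ))
  invisible(x)
}

divergence_error <- function(epoch) {
  structure(
    class = c("triadnet_divergence", "error", "condition"),
    list(message = sprintf("training diverged (non-finite values) at epoch %d", epoch),
         call = NULL, epoch = epoch)
  )
}

#' Run one training simulation
#'
#' Per epoch: draw a fresh batch of `batch_size` training samples, run
#' the forward pass, apply the middle-layer rule and then the common
#' output-layer update (both from the same pre-update forward state),
#' and record the mean squared error on a fixed test set drawn once
#' before epoch 1.  All randomness comes from substreams of
#' `cfg$seed` ([rule_streams()]), so the same seed yields a bitwise
#' identical run and different rules see the same data stream.
#'
#' @param cfg a [train_config()].
#' @return An object of class `training_trace`: list with
#'   `mse_per_epoch` (length-`epochs` vector of test MSE),
#'   `final_params`, `initial_params`, `epochs_run` and `cfg`.
#'   Non-finite weights or errors abort with a condition of class
#'   `triadnet_divergence` carrying the epoch index.
#' @examples
#' tr <- train(train_config(rule = "fa_ex100", epochs = 50, test_n = 200, seed = 1))
#' tr$mse_per_epoch[c(1, 50)]
#' @export
train <- function(cfg) {
  stopifnot(inherits(cfg, "train_config"))
  streams <- rule_streams(cfg$seed)
  spec <- cfg$task
  rule <- cfg$rule$rule

  test_set <- kdxor_dataset(cfg$test_n, spec, streams$data)
  params <- init_params(spec$d, cfg$m, cfg$activation,
                        cfg$init_half_width, streams$init)
  initial_params <- params

  kind <- feedback_kind_for_rule(rule)
  B <- if (!is.null(kind)) make_feedback(kind, cfg$m, streams$feedback) else NULL

  surr <- make_surrogate(cfg$surrogate$kind,
                         param = if (is.null(cfg$surrogate$param)) 0 else cfg$surrogate$param,
                         m = cfg$m, stream = streams$surrogate)
  needs_fprime <- rule %in% c("bp", "fa", "fa_normal", "fa_ex80", "fa_ex100")

  mse <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    batch <- kdxor_dataset(cfg$batch_size, spec, streams$data)
    state <- forward(params, batch$X, batch$y)
    fprime <- if (needs_fprime) {
      eval_surrogate(surr, state$I, cfg$activation, streams$surrogate)
    } else NULL
    params <- apply_rule(rule, params, state, B, fprime,
                         batch = batch, cfg = cfg$rule, streams = streams)
    mse[epoch] <- test_mse(params, test_set)
    if (!is.finite(mse[epoch]) || !all(is.finite(params$W1)) ||
        !all(is.finite(params$b1)) || !all(is.finite(params$W2)) ||
        !is.finite(params$b2)) {
      stop(divergence_error(epoch))
    }
  }

  structure(
    list(mse_per_epoch = mse, final_params = params,
         initial_params = initial_params, epochs_run = cfg$epochs,
         feedback = B, cfg = cfg),
    class = "training_trace"
  )
}

#' @export
print.training_trace <- function(x, ...) {
  ett <- epoch_to_threshold(x, x$cfg$threshold)
  cat(sprintf(
    "training trace: rule = %s, %d epochs, final test MSE = %.4g, epoch to %.3g = %s\n",
    x$cfg$rule$rule, x$epochs_run, x$mse_per_epoch[x$epochs_run],
    x$cfg$threshold, if (is.na(ett)) "censored" else as.character(ett)
  ))
  invisible(x)
}

#' First epoch at which the test MSE crosses a threshold
#'
#' Returns the 1-based index of the first epoch whose test MSE is
#' strictly below `threshold` (not required to stay below), or `NA`
#' (censored) if the curve never crosses within the run.
#'
#' @param trace a [train()] result, or a plain numeric MSE vector.
#' @param threshold positive threshold (default 0.1).
#' @return integer epoch index, or `NA_integer_` if censored.
#' @export
epoch_to_threshold <- function(trace, threshold = 0.1) {
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("`threshold` must be positive", call. = FALSE)
  }
  mse <- if (inherits(trace, "training_trace")) trace$mse_per_epoch else as.numeric(trace)
  idx <- which(mse < threshold)
  if (length(idx) == 0L) NA_integer_ else as.integer(idx[1L])
}

#' Export a training trace as CSV
#'
#' Writes a two-column CSV `(epoch, test_mse)` and, alongside it, a
#' `<path>.json` sidecar echoing the configuration for provenance.
#'
#' @param trace a [train()] result.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "training_trace"))
  utils::write.csv(
    data.frame(epoch = seq_len(trace$epochs_run),
               test_mse = trace$mse_per_epoch),
    path, row.names = FALSE
  )
  cfg <- trace$cfg
  sidecar <- list(
    rule = cfg$rule$rule, eta = cfg$rule$eta, wp_epsilon = cfg$rule$wp_epsilon,
    d = cfg$task$d, k = cfg$task$k, sigma = cfg$task$sigma, m = cfg$m,
    activation = cfg$activation, surrogate = cfg$surrogate,
    batch_size = cfg$batch_size, epochs = cfg$epochs, test_n = cfg$test_n,
    threshold = cfg$threshold, init_half_width = cfg$init_half_width,
    seed = cfg$seed
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
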