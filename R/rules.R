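#' Learning-rule vocabulary
#'
#' The supported middle-layer update rules.  The output-layer update is
#' common to every rule (plain gradient descent on the squared error).
#'
#' * `bp` — backpropagation: the exact chain-rule gradient.
#' * `fa` — feedback alignment: the output-weight vector `W2` in the
#'   middle-layer update is replaced by a fixed uniform `[-1, 1]`
#'   random vector `B`.
#' * `fa_normal`, `fa_ex80`, `fa_ex100` — FA with `B` drawn standard
#'   normal, Bernoulli +/-1 with 80% excitatory (+1) entries, or all
#'   ones, respectively.  With `B` all ones the update is exactly the
#'   three-factor synaptic-triad product
#'   (presynaptic activity x f'(postsynaptic current) x error signal).
#' * `elm` — extreme learning machine: the middle layer is frozen at
#'   its random initialisation.
#' * `wp` — weight perturbation: random Gaussian proposals to the
#'   middle layer, accepted only if the training-batch cost strictly
#'   decreases.
#'
#' Batch aggregation is a sum (not a mean) of per-sample terms, i.e.
#' gradient descent on `J = 0.5 * sum(e^2)` over the batch; halving the
#' batch size therefore roughly doubles the number of epochs needed at
#' a fixed learning rate, leaving the total trial count unchanged.
#' @name learning-rules
NULL

rule_names <- function() c("bp", "fa", "fa_normal", "fa_ex80", "fa_ex100", "elm", "wp")

# which feedback-vector construction an FA-family rule uses
feedback_kind_for_rule <- function(rule) {
  switch(rule,
    fa = "uniform",
    fa_normal = "normal",
    fa_ex80 = "bernoulli_ex80",
    fa_ex100 = "ones",
    NULL
  )
}

#' Rule configuration
#'
#' @param rule one of `"bp"`, `"fa"`, `"fa_normal"`, `"fa_ex80"`,
#'   `"fa_ex100"`, `"elm"`, `"wp"`.
#' @param eta learning rate (per-update step size), > 0.
#' @param wp_epsilon standard deviation of weight-perturbation
#'   proposals; default 0.005.
#' @return an object of class `rule_config`.
#' @export
rule_config <- function(rule, eta, wp_epsilon = 0.005) {
  rule <- match.arg(rule, rule_names())
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta <= 0) {
    stop("`eta` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(wp_epsilon) || wp_epsilon <= 0) {
    stop("`wp_epsilon` must be a positive number", call. = FALSE)
  }
  structure(list(rule = rule, eta = as.double(eta),
                 wp_epsilon = as.double(wp_epsilon)),
            class = "rule_config")
}

#' Construct a feedback vector B
#'
#' `B` replaces `W2` in the middle-layer update of the FA family.  It is
#' fixed at construction and never updated during training.
#'
#' @param kind `"uniform"` (entries uniform on `[-1, 1]`), `"normal"`
#'   (standard normal), `"bernoulli_ex80"` (+1 with probability 0.8,
#'   else -1), or `"ones"` (all entries exactly 1).
#' @param m number of middle-layer neurons.
#' @param stream an [rng_stream()]; unused for `kind = "ones"`.
#' @return an object of class `feedback_vector` with fields `B`
#'   (length-`m` vector) and `kind`.
#' @export
make_feedback <- function(kind = c("uniform", "normal", "bernoulli_ex80", "ones"),
                          m, stream = NULL) {
  kind <- match.arg(kind)
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("`m` must be a positive integer", call. = FALSE)
  B <- switch(kind,
    ones = rep(1, m),
    uniform = stream_eval(stream, stats::runif, m, -1, 1),
    normal = stream_eval(stream, stats::rnorm, m),
    bernoulli_ex80 = stream_eval(stream, function() {
      ifelse(stats::runif(m) < 0.8, 1, -1)
    })
  )
  structure(list(B = B, kind = kind), class = "feedback_vector")
}

as_feedback_values <- function(B) {
  if (inherits(B, "feedback_vector")) B$B else as.double(B)
}

#' Output-layer weight update (common to all rules)
#'
#' Gradient descent on the batch cost `J = 0.5 * sum(e^2)`:
#' `dW2 = eta * sum_n e_n * h_n` and `db2 = eta * sum_n e_n`, summed
#' (not averaged) over the batch.
#'
#' @param state a [forward()] state computed on the current batch.
#' @param eta learning rate.
#' @return `output_delta`: length-`m` update vector `dW2`;
#'   `output_bias_delta`: scalar update `db2`.
#' @export
output_delta <- function(state, eta) {
  stopifnot(inherits(state, "forward_state"))
  eta * drop(crossprod(state$h, state$e))
}

#' @rdname output_delta
#' @export
output_bias_delta <- function(state, eta) {
  stopifnot(inherits(state, "forward_state"))
  eta * sum(state$e)
}

#' Middle-layer updates: backpropagation and feedback alignment
#'
#' Backpropagation uses the exact gradient of the batch cost,
#' `dW1[j, i] = eta * sum_n e_n * W2_j * f'(I_nj) * x_ni`, and the
#' corresponding bias update with presynaptic activity 1.
#' Feedback alignment replaces `W2` by the fixed feedback vector `B`;
#' with `B` all ones this is the pure three-factor product
#' `presynaptic x f'(current) x error`.
#'
#' @param state a [forward()] state for the batch.
#' @param params a [init_params()] object (supplies `W2` for BP).
#' @param B a [make_feedback()] object or plain numeric vector.
#' @param fprime_vals `n x m` matrix of (possibly surrogate) derivative
#'   values evaluated at `state$I`.
#' @param X the `n x d` batch inputs.
#' @param eta learning rate.
#' @return `middle_delta_*`: `m x d` update matrix `dW1`;
#'   `middle_bias_delta_*`: length-`m` update vector `db1`.
#' @export
middle_delta_bp <- function(state, params, fprime_vals, X, eta) {
  middle_delta_fa(state, params$W2, fprime_vals, X, eta)
}

#' @rdname middle_delta_bp
#' @export
middle_delta_fa <- function(state, B, fprime_vals, X, eta) {
  stopifnot(inherits(state, "forward_state"))
  b <- as_feedback_values(B)
  X <- as.matrix(X)
  fprime_vals <- as.matrix(fprime_vals)
  if (!all(dim(fprime_vals) == dim(state$I))) {
    stop("fprime_vals must match the shape of state$I", call. = FALSE)
  }
  if (length(b) != ncol(fprime_vals)) {
    stop("feedback vector length must equal the number of middle neurons",
         call. = FALSE)
  }
  # M[n, j] = e_n * B_j * f'(I_nj); dW1 = eta * M' X  (sum over the batch)
  M <- fprime_vals * tcrossprod(state$e, b)
  eta * crossprod(M, X)
}

#' @rdname middle_delta_bp
#' @export
middle_bias_delta_bp <- function(state, params, fprime_vals, eta) {
  middle_bias_delta_fa(state, params$W2, fprime_vals, eta)
}

#' @rdname middle_delta_bp
#' @export
middle_bias_delta_fa <- function(state, B, fprime_vals, eta) {
  drop(middle_delta_fa(state, B, fprime_vals,
                       matrix(1, nrow(as.matrix(fprime_vals)), 1L), eta))
}

#' Weight-perturbation step
#'
#' Proposes a full candidate update to the middle layer (weights and
#' biases) with i.i.d. Gaussian entries of standard deviation
#' `wp_epsilon` and accepts it iff the batch squared-error cost with
#' the perturbed middle layer (output layer held fixed) is strictly
#' lower than without it.  Ties reject.
#'
#' @param params a [init_params()] object.
#' @param X,y the current training batch.
#' @param wp_epsilon proposal standard deviation.
#' @param stream an [rng_stream()] for the proposal.
#' @return list with `delta_W1` (`m x d`), `delta_b1` (length `m`) and
#'   `accepted` (logical).
#' @export
wp_step <- function(params, X, y, wp_epsilon, stream) {
  prop <- stream_eval(stream, function() {
    list(
      delta_W1 = matrix(stats::rnorm(params$m * params$d, sd = wp_epsilon),
                        params$m, params$d),
      delta_b1 = stats::rnorm(params$m, sd = wp_epsilon)
    )
  })
  cost_old <- batch_cost(params, X, y)
  cand <- params
  cand$W1 <- params$W1 + prop$delta_W1
  cand$b1 <- params$b1 + prop$delta_b1
  cost_new <- batch_cost(cand, X, y)
  list(delta_W1 = prop$delta_W1, delta_b1 = prop$delta_b1,
       accepted = cost_new < cost_old)
}

#' Apply one learning-rule update
#'
#' Performs the middle-layer update for `rule` followed by the common
#' output-layer update, both computed from the same pre-update forward
#' state (simultaneous-update semantics).  `elm` leaves the middle
#' layer untouched; `wp` runs [wp_step()] with the output layer frozen
#' at its pre-update value.
#'
#' @param rule rule name (see [rule_config()]).
#' @param params current [init_params()] object.
#' @param state [forward()] state on the batch.
#' @param B feedback vector (FA family; ignored otherwise).
#' @param fprime_vals surrogate derivative values at `state$I`
#'   (bp/fa family; ignored otherwise).
#' @param batch list with `X`, `y` for the batch.
#' @param cfg a [rule_config()].
#' @param streams substream list from [rule_streams()] (used by `wp`).
#' @return the updated `network_params`.
#' @export
apply_rule <- function(rule, params, state, B = NULL, fprime_vals = NULL,
                       batch = NULL, cfg, streams = NULL) {
  rule <- match.arg(rule, rule_names())
  middle <- switch(rule,
    elm = NULL,
    wp = {
      step <- wp_step(params, batch$X, batch$y, cfg$wp_epsilon, streams$wp)
      if (step$accepted) list(dW1 = step$delta_W1, db1 = step$delta_b1) else NULL
    },
    bp = list(
      dW1 = middle_delta_bp(state, params, fprime_vals, batch$X, cfg$eta),
      db1 = middle_bias_delta_bp(state, params, fprime_vals, cfg$eta)
    ),
    # fa, fa_normal, fa_ex80, fa_ex100
    list(
      dW1 = middle_delta_fa(state, B, fprime_vals, batch$X, cfg$eta),
      db1 = middle_bias_delta_fa(state, B, fprime_vals, cfg$eta)
    )
  )
  dW2 <- output_delta(state, cfg$eta)
  db2 <- output_bias_delta(state, cfg$eta)
  if (!is.null(middle)) {
    params$W1 <- params$W1 + middle$dW1
    params$b1 <- params$b1 + middle$db1
  }
  params$W2 <- params$W2 + dW2
  params$b2 <- params$b2 + db2
  params
}
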