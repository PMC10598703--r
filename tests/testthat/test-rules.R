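test_that("feedback vectors follow their declared distributions", {
  expect_equal(make_feedback("ones", 20)$B, rep(1, 20))
  u <- make_feedback("uniform", 1000, rng_stream(1))$B
  expect_true(all(u >= -1 & u <= 1))
  bern <- make_feedback("bernoulli_ex80", 1e5, rng_stream(2))$B
  expect_true(all(bern %in% c(-1, 1)))
  expect_equal(mean(bern == 1), 0.8, tolerance = 0.01)
  nrm <- make_feedback("normal", 1e5, rng_stream(3))$B
  expect_equal(stats::sd(nrm), 1, tolerance = 0.02)
  expect_error(make_feedback("laplace", 5), "arg")
})

test_that("output update is the forced arithmetic and vanishes at convergence", {
  st <- structure(list(h = matrix(c(1, 0), 1), e = 0.5, I = matrix(c(1, -1), 1),
                       yhat = 0.5), class = "forward_state")
  expect_equal(output_delta(st, 0.005), c(0.0025, 0))
  expect_equal(output_bias_delta(st, 0.005), 0.0025)
  st0 <- st; st0$e <- 0
  expect_equal(output_delta(st0, 0.01), c(0, 0))
})

test_that("BP deltas equal minus eta times the finite-difference gradient", {
  for (seed in c(1, 2)) {
    act <- if (seed == 1) "tanh" else "relu"
    inst <- random_instance(seed, activation = act)
    s <- forward(inst$params, inst$X, inst$y)
    fp <- activation_deriv(act, s$I)
    eta <- 0.37
    g <- fd_gradient(inst$params, inst$X, inst$y)
    expect_equal(middle_delta_bp(s, inst$params, fp, inst$X, eta), -eta * g$W1,
                 tolerance = 1e-6)
    expect_equal(middle_bias_delta_bp(s, inst$params, fp, eta), -eta * g$b1,
                 tolerance = 1e-6)
    expect_equal(output_delta(s, eta), -eta * g$W2, tolerance = 1e-6)
    expect_equal(output_bias_delta(s, eta), -eta * g$b2, tolerance = 1e-6)
  }
})

test_that("FA with B set to W2 reproduces BP exactly", {
  inst <- random_instance(3, activation = "relu")
  s <- forward(inst$params, inst$X, inst$y)
  fp <- activation_deriv("relu", s$I)
  expect_identical(
    middle_delta_fa(s, inst$params$W2, fp, inst$X, 0.01),
    middle_delta_bp(s, inst$params, fp, inst$X, 0.01)
  )
})

test_that("FA deltas are the three-factor product and linear in B", {
  # single sample, x_i = 1, f' = 1, e = 0.5, eta = 0.005 -> each entry 0.0025
  s <- structure(list(I = matrix(1, 1, 2), h = matrix(1, 1, 2),
                      yhat = 0.5, e = 0.5), class = "forward_state")
  d1 <- middle_delta_fa(s, c(1, 1), matrix(1, 1, 2), matrix(1, 1, 3), 0.005)
  expect_equal(d1, matrix(0.0025, 2, 3), ignore_attr = TRUE)
  # flipping one feedback entry flips that row of the update
  d2 <- middle_delta_fa(s, c(1, -1), matrix(1, 1, 2), matrix(1, 1, 3), 0.005)
  expect_equal(d2[1, ], d1[1, ])
  expect_equal(d2[2, ], -d1[2, ])
})

test_that("FA_Ex-100% updates use only synaptic-triad information", {
  # recompute the update from (x, f'(I), e, eta) alone - no W1, W2 or B
  inst <- random_instance(8, activation = "relu")
  s <- forward(inst$params, inst$X, inst$y)
  fp <- activation_deriv("relu", s$I)
  eta <- 0.01
  got <- middle_delta_fa(s, make_feedback("ones", inst$params$m), fp, inst$X, eta)
  triad <- matrix(0, inst$params$m, inst$params$d)
  for (j in seq_len(inst$params$m)) {
    for (i in seq_len(inst$params$d)) {
      triad[j, i] <- eta * sum(s$e * fp[, j] * inst$X[, i])
    }
  }
  expect_equal(got, triad, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("weight perturbation accepts iff the batch cost strictly decreases", {
  inst <- random_instance(5, activation = "relu")
  st <- rng_stream(99)
  n_acc <- 0
  p <- inst$params
  for (i in 1:30) {
    before <- triadnet:::batch_cost(p, inst$X, inst$y)
    step <- wp_step(p, inst$X, inst$y, wp_epsilon = 0.05, stream = st)
    cand <- p
    cand$W1 <- p$W1 + step$delta_W1
    cand$b1 <- p$b1 + step$delta_b1
    after <- triadnet:::batch_cost(cand, inst$X, inst$y)
    expect_identical(step$accepted, after < before)
    if (step$accepted) {
      expect_lt(after, before)  # accepted-move cost monotonicity
      p <- cand
      n_acc <- n_acc + 1
    }
  }
  expect_gt(n_acc, 0)
})

test_that("apply_rule freezes the middle layer for ELM and updates it otherwise", {
  inst <- random_instance(7, activation = "relu")
  s <- forward(inst$params, inst$X, inst$y)
  fp <- activation_deriv("relu", s$I)
  cfg <- rule_config("elm", eta = 0.01)
  batch <- list(X = inst$X, y = inst$y)
  out <- apply_rule("elm", inst$params, s, NULL, NULL, batch, cfg)
  expect_identical(out$W1, inst$params$W1)
  expect_identical(out$b1, inst$params$b1)
  expect_false(identical(out$W2, inst$params$W2))
  out_bp <- apply_rule("bp", inst$params, s, NULL, fp, batch, rule_config("bp", 0.01))
  expect_false(identical(out_bp$W1, inst$params$W1))
  expect_error(apply_rule("adam", inst$params, s, NULL, fp, batch, cfg))
})

test_that("one small BP step descends the batch cost", {
  inst <- random_instance(10, activation = "tanh")
  s <- forward(inst$params, inst$X, inst$y)
  fp <- activation_deriv("tanh", s$I)
  batch <- list(X = inst$X, y = inst$y)
  before <- triadnet:::batch_cost(inst$params, inst$X, inst$y)
  out <- apply_rule("bp", inst$params, s, NULL, fp, batch, rule_config("bp", 1e-4))
  expect_lt(triadnet:::batch_cost(out, inst$X, inst$y), before)
})

test_that("rule configuration validates its numeric fields", {
  expect_error(rule_config("bp", eta = 0), "eta")
  expect_error(rule_config("bp", eta = -1), "eta")
  expect_error(rule_config("wp", eta = 0.01, wp_epsilon = 0), "wp_epsilon")
  cfg <- rule_config("wp", eta = 0.01)
  expect_equal(cfg$wp_epsilon, 0.005)
})
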