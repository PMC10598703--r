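small_cfg <- function(rule = "bp", epochs = 40, seed = 1, ...) {
  train_config(d = 6, k = 2, m = 8, rule = rule, activation = "relu",
               epochs = epochs, test_n = 100, seed = seed, ...)
}

test_that("training is bitwise reproducible from the master seed", {
  tr1 <- train(small_cfg("fa"))
  tr2 <- train(small_cfg("fa"))
  expect_identical(tr1$mse_per_epoch, tr2$mse_per_epoch)
  expect_identical(tr1$final_params, tr2$final_params)
  tr3 <- train(small_cfg("fa", seed = 2))
  expect_false(identical(tr1$mse_per_epoch, tr3$mse_per_epoch))
})

test_that("substreams give every rule the same data and initial network", {
  rules <- c("bp", "fa", "elm", "wp", "fa_ex100")
  inits <- lapply(rules, function(r) train(small_cfg(r))$initial_params)
  for (i in 2:length(inits)) expect_identical(inits[[1]], inits[[i]])
})

test_that("the epoch loop matches an independent replay of the protocol", {
  cfg <- small_cfg("fa_ex100", epochs = 25)
  tr <- train(cfg)
  # replay: same substream discipline, explicit update order
  streams <- rule_streams(cfg$seed)
  test_set <- kdxor_dataset(cfg$test_n, cfg$task, streams$data)
  p <- init_params(cfg$task$d, cfg$m, cfg$activation,
                   cfg$init_half_width, streams$init)
  B <- make_feedback("ones", cfg$m, streams$feedback)
  n_samples <- 0
  mse <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    batch <- kdxor_dataset(cfg$batch_size, cfg$task, streams$data)
    n_samples <- n_samples + nrow(batch$X)
    s <- forward(p, batch$X, batch$y)
    fp <- activation_deriv(cfg$activation, s$I)
    p$W1 <- p$W1 + middle_delta_fa(s, B, fp, batch$X, cfg$rule$eta)
    p$b1 <- p$b1 + middle_bias_delta_fa(s, B, fp, cfg$rule$eta)
    p$W2 <- p$W2 + output_delta(s, cfg$rule$eta)
    p$b2 <- p$b2 + output_bias_delta(s, cfg$rule$eta)
    mse[ep] <- test_mse(p, test_set)
  }
  expect_identical(tr$mse_per_epoch, mse)
  expect_identical(tr$final_params, p)
  # trial-count identity: samples consumed = epochs x batch_size
  expect_equal(n_samples, cfg$epochs * cfg$batch_size)
})

test_that("ELM leaves the middle layer bitwise untouched over training", {
  tr <- train(small_cfg("elm", epochs = 60))
  expect_identical(tr$final_params$W1, tr$initial_params$W1)
  expect_identical(tr$final_params$b1, tr$initial_params$b1)
  expect_false(identical(tr$final_params$W2, tr$initial_params$W2))
})

test_that("epoch_to_threshold returns the first crossing or a censored NA", {
  expect_equal(epoch_to_threshold(c(0.5, 0.2, 0.09, 0.12), 0.1), 3L)
  expect_identical(epoch_to_threshold(c(0.5, 0.2, 0.15), 0.1), NA_integer_)
  expect_equal(epoch_to_threshold(c(0.05, 0.2), 0.1), 1L)
  expect_error(epoch_to_threshold(c(0.5), 0), "positive")
  tr <- train(small_cfg("fa", epochs = 30))
  expect_identical(epoch_to_threshold(tr, 0.1),
                   epoch_to_threshold(tr$mse_per_epoch, 0.1))
})

test_that("learning curves improve for gradient-family rules", {
  res <- run_replicates(small_cfg("bp", epochs = 150), n_seeds = 5)
  expect_lt(stats::median(res$traces[150, ]), res$mean_curve[1])
  expect_true(all(is.finite(res$mean_curve)) && all(res$mean_curve >= 0))
})

test_that("halving the batch size roughly doubles BP's epochs to threshold", {
  cfg8 <- train_config(d = 12, k = 2, m = 20, rule = "bp", activation = "relu",
                       batch_size = 8, epochs = 700, test_n = 300)
  cfg4 <- train_config(d = 12, k = 2, m = 20, rule = "bp", activation = "relu",
                       batch_size = 4, epochs = 700, test_n = 300)
  r8 <- run_replicates(cfg8, n_seeds = 10, base_seed = 1)
  r4 <- run_replicates(cfg4, n_seeds = 10, base_seed = 1)
  ratio <- r4$mean_epoch_to_threshold / r8$mean_epoch_to_threshold
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 2.8)
})

test_that("divergence raises a typed error carrying the epoch index", {
  # FA at high noise dimension under the sum-aggregated step is unstable
  cfg <- train_config(d = 202, k = 2, m = 20, rule = "fa", activation = "relu",
                      eta = 0.01, epochs = 300, test_n = 50, seed = 1)
  err <- tryCatch(train(cfg), triadnet_divergence = function(e) e)
  expect_s3_class(err, "triadnet_divergence")
  expect_true(is.numeric(err$epoch) && err$epoch >= 1)
})

test_that("trace CSV export round-trips the learning curve with a config sidecar", {
  path <- withr::local_tempfile(fileext = ".csv")
  tr <- train(small_cfg("fa", epochs = 15))
  write_trace_csv(tr, path)
  back <- utils::read.csv(path)
  expect_equal(back$test_mse, tr$mse_per_epoch)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$rule, "fa")
  expect_equal(side$seed, 1)
})

test_that("config validation enforces the protocol invariants", {
  expect_error(train_config(epochs = 0), "positive")
  expect_error(train_config(batch_size = 0), "positive")
  expect_error(train_config(threshold = -0.1), "positive")
  cfg <- train_config(activation = "tanh")
  expect_equal(cfg$rule$eta, 0.02)   # activation-dependent default
  expect_equal(train_config(activation = "relu")$rule$eta, 0.01)
  expect_equal(cfg$batch_size, 8L)
  expect_equal(cfg$epochs, 1000L)
})
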