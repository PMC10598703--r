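#' Seed-replicated training runs
#'
#' Runs the same configuration under `n_seeds` consecutive master
#' seeds (`base_seed .. base_seed + n_seeds - 1`); every seed draws its
#' own data, initial weights, feedback vector and noise.  Aggregates
#' the learning curves (mean and population standard deviation over
#' non-diverged seeds, per epoch) and the per-seed epoch-to-threshold
#' statistics.  A diverged seed is recorded as censored, not fatal.
#'
#' @param cfg a [train_config()]; its `seed` field is overridden.
#' @param n_seeds number of replicate seeds.
#' @param base_seed first master seed.
#' @return An object of class `replicate_result`: list with `cfg`,
#'   `seeds`, `traces` (an `epochs x n_seeds` matrix of test MSE, NA
#'   columns for diverged seeds), `mean_curve`, `sd_curve`,
#'   `epochs_to_threshold` (per-seed, NA = censored),
#'   `mean_epoch_to_threshold` (over crossing seeds),
#'   `n_censored`, `n_diverged`.
#' @export
run_replicates <- function(cfg, n_seeds = 20, base_seed = 1) {
  stopifnot(inherits(cfg, "train_config"))
  n_seeds <- as.integer(n_seeds)
  if (is.na(n_seeds) || n_seeds < 1L) {
    stop("`n_seeds` must be a positive integer", call. = FALSE)
  }
  seeds <- as.integer(base_seed) + seq_len(n_seeds) - 1L
  traces <- matrix(NA_real_, cfg$epochs, n_seeds)
  ett <- rep(NA_integer_, n_seeds)
  diverged <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg_i <- cfg
    cfg_i$seed <- seeds[i]
    tr <- tryCatch(train(cfg_i), triadnet_divergence = function(e) e)
    if (inherits(tr, "triadnet_divergence")) {
      diverged[i] <- TRUE
    } else {
      traces[, i] <- tr$mse_per_epoch
      ett[i] <- epoch_to_threshold(tr, cfg$threshold)
    }
  }
  ok <- !diverged
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(
    list(
      cfg = cfg, seeds = seeds, traces = traces,
      mean_curve = rowMeans(traces[, ok, drop = FALSE]),
      sd_curve = apply(traces[, ok, drop = FALSE], 1L, pop_sd),
      epochs_to_threshold = ett,
      mean_epoch_to_threshold =
        if (any(!is.na(ett))) mean(ett, na.rm = TRUE) else NA_real_,
      n_censored = sum(is.na(ett)),
      n_diverged = sum(diverged)
    ),
    class = "replicate_result"
  )
}

#' @export
print.replicate_result <- function(x, ...) {
  cat(sprintf(
    "replicates: rule = %s, %d seeds, min mean MSE = %.4g, mean epoch-to-%.3g = %s (%d censored)\n",
    x$cfg$rule$rule, length(x$seeds), min(x$mean_curve), x$cfg$threshold,
    if (is.na(x$mean_epoch_to_threshold)) "NA"
    else sprintf("%.1f", x$mean_epoch_to_threshold),
    x$n_censored
  ))
  invisible(x)
}

#' Run a list of configurations with seed replication
#'
#' @param configs list of [train_config()] objects.
#' @param n_seeds,base_seed see [run_replicates()].
#' @param figure_id optional label attached to the result.
#' @return An object of class `experiment_result`: list with
#'   `figure_id`, `configs` and `results` (one [run_replicates()]
#'   result per configuration).
#' @export
run_experiment <- function(configs, n_seeds = 20, base_seed = 1,
                           figure_id = NA_character_) {
  stopifnot(length(configs) >= 1L)
  results <- lapply(configs, run_replicates,
                    n_seeds = n_seeds, base_seed = base_seed)
  structure(
    list(figure_id = figure_id, configs = configs, results = results),
    class = "experiment_result"
  )
}

# default sweep grids for the derivative-surrogate robustness study
surrogate_grids <- function() {
  list(
    y_shift = c(-0.5, -0.25, 0, 0.25, 0.5),
    x_shift = c(-0.2, -0.1, 0, 0.1, 0.2, 0.5),
    y_scale = c(0.5, 1, 2, 4),
    sigmoid_slope = c(1, 5, 10, 50),
    noise = c(0, 0.1, 0.3, 0.5, 1.0)
  )
}

#' Preset configuration sets for the benchmark figures
#'
#' `fig1` compares BP, FA, WP and ELM on the 12-input task (k = 2,
#' 10 noise inputs) over four network settings: tanh or ReLU hidden
#' units with 10 or 20 middle-layer neurons (eta = 0.02 for tanh, 0.01
#' for ReLU).  `fig2` compares BP, FA, FA_normal, FA_Ex-80% and
#' FA_Ex-100% (ReLU, m = 20, eta = 0.01) at noise input dimensions 50,
#' 100 and 200.  `fig3`..`fig7` sweep the derivative surrogates
#' (y-shift, x-shift, y-scale, sigmoid slope, unfixed/fixed additive
#' noise) for FA_Ex-100% on the 12-input task with ReLU, m = 20 and
#' eta = 0.005.
#'
#' @param figure_id one of `"fig1"` .. `"fig7"`.
#' @param grids named list of surrogate parameter grids overriding the
#'   defaults (`y_shift`, `x_shift`, `y_scale`, `sigmoid_slope`,
#'   `noise`).
#' @return list of [train_config()] objects.
#' @examples
#' length(preset("fig2"))  # 5 rules x 3 noise dimensions
#' @export
preset <- function(figure_id, grids = list()) {
  figure_id <- match.arg(figure_id, paste0("fig", 1:7))
  g <- utils::modifyList(surrogate_grids(), grids)
  if (figure_id == "fig1") {
    configs <- list()
    for (net in list(list(activation = "tanh", m = 10, eta = 0.02),
                     list(activation = "tanh", m = 20, eta = 0.02),
                     list(activation = "relu", m = 10, eta = 0.01),
                     list(activation = "relu", m = 20, eta = 0.01))) {
      for (rule in c("bp", "fa", "wp", "elm")) {
        configs[[length(configs) + 1L]] <- train_config(
          d = 12, k = 2, m = net$m, rule = rule,
          activation = net$activation, eta = net$eta
        )
      }
    }
    return(configs)
  }
  if (figure_id == "fig2") {
    configs <- list()
    for (d_noise in c(50, 100, 200)) {
      for (rule in c("bp", "fa", "fa_normal", "fa_ex80", "fa_ex100")) {
        configs[[length(configs) + 1L]] <- train_config(
          d = 2 + d_noise, k = 2, m = 20, rule = rule,
          activation = "relu", eta = 0.01
        )
      }
    }
    return(configs)
  }
  # fig3..fig7: surrogate sweeps, FA_Ex-100%, relu, m = 20, eta = 0.005
  sweep_spec <- switch(figure_id,
    fig3 = list(kinds = "y_shift", grid = g$y_shift),
    fig4 = list(kinds = "x_shift", grid = g$x_shift),
    fig5 = list(kinds = "y_scale", grid = g$y_scale),
    fig6 = list(kinds = "sigmoid_slope", grid = g$sigmoid_slope),
    fig7 = list(kinds = c("noise_unfixed", "noise_fixed"), grid = g$noise)
  )
  configs <- list()
  for (kind in sweep_spec$kinds) {
    for (p in sweep_spec$grid) {
      configs[[length(configs) + 1L]] <- train_config(
        d = 12, k = 2, m = 20, rule = "fa_ex100", activation = "relu",
        eta = 0.005, surrogate = list(kind = kind, param = p)
      )
    }
  }
  configs
}

#' Export experiment results as tidy CSV
#'
#' Writes `curves.csv` with one row per (configuration, seed, epoch)
#' and columns `figure_id, rule, activation, m, d, d_noise, eta,
#' surrogate_kind, surrogate_param, seed, epoch, test_mse`, plus
#' `summary.csv` with one row per (configuration, seed) holding the
#' epoch-to-threshold (NA = censored).  Mean/sd curves are recoverable
#' from `curves.csv` alone.
#'
#' @param result an [run_experiment()] result (a single
#'   [run_replicates()] result is promoted).
#' @param dir output directory (created if needed).
#' @return named character vector of the two file paths, invisibly.
#' @export
export_csv <- function(result, dir) {
  if (inherits(result, "replicate_result")) {
    result <- structure(
      list(figure_id = NA_character_, configs = list(result$cfg),
           results = list(result)),
      class = "experiment_result"
    )
  }
  stopifnot(inherits(result, "experiment_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  cfg_row <- function(cfg) {
    data.frame(
      figure_id = result$figure_id, rule = cfg$rule$rule,
      activation = cfg$activation, m = cfg$m, d = cfg$task$d,
      d_noise = cfg$task$d_noise, eta = cfg$rule$eta,
      surrogate_kind = cfg$surrogate$kind,
      surrogate_param = if (is.null(cfg$surrogate$param)) 0 else cfg$surrogate$param,
      stringsAsFactors = FALSE
    )
  }

  curves <- list()
  summaries <- list()
  for (res in result$results) {
    base <- cfg_row(res$cfg)
    for (i in seq_along(res$seeds)) {
      if (all(is.na(res$traces[, i]))) next  # diverged seed
      curves[[length(curves) + 1L]] <- cbind(
        base, seed = res$seeds[i],
        epoch = seq_len(nrow(res$traces)),
        test_mse = res$traces[, i],
        row.names = NULL
      )
    }
    summaries[[length(summaries) + 1L]] <- cbind(
      base, seed = res$seeds,
      epoch_to_threshold = res$epochs_to_threshold,
      diverged = all_na_cols(res$traces),
      row.names = NULL
    )
  }
  curves_path <- file.path(dir, "curves.csv")
  summary_path <- file.path(dir, "summary.csv")
  utils::write.csv(do.call(rbind, curves), curves_path, row.names = FALSE)
  utils::write.csv(do.call(rbind, summaries), summary_path, row.names = FALSE)
  invisible(c(curves = curves_path, summary = summary_path))
}

all_na_cols <- function(m) apply(m, 2L, function(x) all(is.na(x)))
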