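# Small in-code fixtures shared across the suite.

# a short gap-free series with simple dynamics, one patient
toy_series <- function(n = 200, bg = NULL, split_at = NULL, pid = "p1") {
  if (is.null(bg)) bg <- 120 + 40 * sin(seq_len(n) / 12)
  split <- if (is.null(split_at)) NULL else {
    c(rep("train", split_at), rep("test", n - split_at))
  }
  cgm_series(pid, bg = bg, bas = rep(1, n),
             bol = ifelse(seq_len(n) %% 37 == 0, 4, 0),
             ch = ifelse(seq_len(n) %% 37 == 0, 40, 0),
             split = split)
}

# a quick simulated, preprocessed, windowed single patient
toy_windows <- function(days = 3, seed = 5, horizons = c(30, 60, 120)) {
  cfg <- sim_config(n_patients = 1, days = days, seed = seed)
  s <- fill_gaps(simulate_cohort(cfg))
  make_windows(scale_features(s), horizons = horizons)
}

# fast protocol for tests that only need the training loop mechanics
quick_protocol <- function(max_epochs = 3, seed = 1) {
  training_protocol(max_epochs = max_epochs, patience = 10,
                    batch_size = 32, folds = 2, seed = seed)
}

# naive-loop implementations of the seven metrics, kept deliberately
# independent of compute_metrics()
oracle_metrics <- function(actual, predicted) {
  n <- length(actual)
  mse <- 0; mae <- 0; mard <- 0
  for (t in seq_len(n)) {
    mse <- mse + (predicted[t] - actual[t])^2 / n
    mae <- mae + abs(predicted[t] - actual[t]) / n
    mard <- mard + abs(predicted[t] - actual[t]) / actual[t] / n
  }
  abar <- sum(actual) / n
  pbar <- sum(predicted) / n
  sst <- 0; sabs <- 0; num <- 0; dp <- 0; da <- 0
  for (t in seq_len(n)) {
    sst <- sst + (actual[t] - abar)^2
    sabs <- sabs + abs(actual[t] - abar)
    num <- num + (predicted[t] - pbar) * (actual[t] - abar)
    dp <- dp + (predicted[t] - pbar)^2
    da <- da + (actual[t] - abar)^2
  }
  list(mse = mse, rmse = sqrt(mse), mae = mae,
       r2 = 1 - sum((predicted - actual)^2) / sst,
       cc = num / sqrt(dp * da),
       fit = 1 - sum(abs(predicted - actual)) / sabs,
       mard = mard)
}
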