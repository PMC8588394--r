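# Gradient correctness of the layer engine: analytic backprop versus central
# finite differences through the full graph, per architecture family.

num_vs_analytic <- function(spec_id, B = 3, eps = 1e-5, n_checks = 5) {
  model <- build_model(spec_id, seed = 99)
  set.seed(101)
  X <- array(runif(B * 25 * 4), dim = c(B, 25, 4))
  y <- if (model$loss == "categorical") sample(0:99, B) else runif(B, 0.8, 2)
  loss_of <- function(m) {
    out <- glybench:::forward_graph(m, X, training = TRUE)$out
    glybench:::loss_forward_backward(m$loss, as.matrix(out), y)$loss
  }
  fc <- glybench:::forward_graph(model, X, training = TRUE)
  lb <- glybench:::loss_forward_backward(model$loss, as.matrix(fc$out), y)
  grads <- glybench:::backward_graph(model, fc$caches, lb$dout)
  worst <- 0
  for (id in names(grads)) {
    for (pn in names(grads[[id]])) {
      w <- model$nodes[[id]]$layer$params[[pn]]
      gan <- grads[[id]][[pn]]
      for (j in sample(length(w), min(n_checks, length(w)))) {
        m2 <- model
        m2$nodes[[id]]$layer$params[[pn]][j] <- w[j] + eps
        lp <- loss_of(m2)
        m2$nodes[[id]]$layer$params[[pn]][j] <- w[j] - eps
        lm <- loss_of(m2)
        gn <- (lp - lm) / (2 * eps)
        worst <- max(worst, abs(gn - gan[j]) /
                       max(1e-6, abs(gn) + abs(gan[j])))
      }
    }
  }
  worst
}

test_that("backpropagation matches numerical gradients in every layer type", {
  # together these cover dense, conv/pool, plain & stacked/dilated RNN,
  # LSTM (seq and last-state), BiLSTM, batchnorm, concat branches, and the
  # three loss heads
  for (sp in c("mirshekarian", "meijner", "gulesir", "sun", "zhu", "mayo",
               "munoz", "aiello")) {
    expect_lt(num_vs_analytic(sp), 1e-4, label = paste("grad err", sp))
  }
})

test_that("training is deterministic given the seed", {
  ds <- toy_windows(days = 2, seed = 4, horizons = 30)
  tr <- which(ds$meta$partition == "train")
  p <- fold_partition(length(tr), 2, 0.8)[[1]]
  trd <- windows_subset(windows_subset(ds, tr), p$train)
  vad <- windows_subset(windows_subset(ds, tr), p$val)
  f1 <- train_model("mirshekarian", trd, vad, 30, quick_protocol(3, seed = 7))
  f2 <- train_model("mirshekarian", trd, vad, 30, quick_protocol(3, seed = 7))
  expect_identical(f1$model$nodes$lstm1$layer$params,
                   f2$model$nodes$lstm1$layer$params)
  expect_equal(f1$history, f2$history)
})

test_that("early stopping restores the best epoch and respects patience", {
  ds <- toy_windows(days = 2, seed = 4, horizons = 30)
  tr <- which(ds$meta$partition == "train")
  p <- fold_partition(length(tr), 2, 0.8)[[1]]
  trd <- windows_subset(windows_subset(ds, tr), p$train)
  vad <- windows_subset(windows_subset(ds, tr), p$val)
  fit <- train_model("mirshekarian", trd, vad, 30,
                     training_protocol(max_epochs = 40, patience = 3,
                                       batch_size = 64, seed = 2))
  h <- fit$history
  best <- which.min(h$val_loss)
  # ran at most `patience` epochs past the best epoch
  expect_lte(nrow(h), best + 3)
  # restored weights reproduce the best validation loss
  ev <- glybench:::evaluate_graph(
    fit$model, vad$inputs,
    glybench:::loss_target(fit$model, vad$targets[["30"]]),
    vad$targets[["30"]], vad$scale_stats, vad$bg_minmax)
  expect_equal(ev$loss, min(h$val_loss), tolerance = 1e-10)
})

test_that("a constant-target signal is learned to within 2 mg/dL", {
  # degenerate learnable problem: constant glucose
  s <- scale_features(toy_series(400, bg = rep(120, 400), split_at = 320))
  ds <- make_windows(s, horizons = 30)
  tr <- which(ds$meta$partition == "train")
  te <- which(ds$meta$partition == "test")
  p <- fold_partition(length(tr), 2, 0.8)[[1]]
  trd <- windows_subset(windows_subset(ds, tr), p$train)
  vad <- windows_subset(windows_subset(ds, tr), p$val)
  fit <- train_model("mirshekarian", trd, vad, 30,
                     training_protocol(max_epochs = 30, batch_size = 32,
                                       seed = 5))
  pred <- predict(fit, windows_subset(ds, te))
  expect_true(all(abs(pred - 120) < 2))
})

test_that("divergent training reports the failing spec", {
  ds <- toy_windows(days = 2, seed = 4, horizons = 30)
  tr <- which(ds$meta$partition == "train")
  p <- fold_partition(length(tr), 2, 0.8)[[1]]
  trd <- windows_subset(windows_subset(ds, tr), p$train)
  vad <- windows_subset(windows_subset(ds, tr), p$val)
  # corrupt weights propagate as a training-failure error naming the spec
  m <- build_model("mirshekarian", seed = 1)
  m$nodes$out$layer$params$W[] <- NaN
  expect_error(
    train_model(m, trd, vad, 30,
                training_protocol(max_epochs = 2, batch_size = 32, seed = 1)),
    "mirshekarian")
})
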