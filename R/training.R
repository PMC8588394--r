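#' The uniform training protocol
#'
#' Every architecture is trained under identical conditions (only the loss
#' differs per spec): Adam with learning rate 0.01, at most 100 epochs with
#' early stopping at 10 epochs' patience on the validation loss (best epoch
#' restored), and 10 repetitions of a contiguous 80/20 train/validation
#' split with shifting block origin.
#'
#' @param learning_rate Adam learning rate.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience, epochs.
#' @param batch_size Mini-batch size.
#' @param folds Number of cross-validation repetitions.
#' @param train_fraction Fraction of training windows used for fitting in
#'   each fold (the remainder validates).
#' @param seed Integer seed governing initialization and batch shuffling.
#' @return A `training_protocol` list.
#' @export
training_protocol <- function(learning_rate = 0.01, max_epochs = 100,
                              patience = 10, batch_size = 64, folds = 10,
                              train_fraction = 0.8, seed = 1L) {
  stopifnot(learning_rate > 0, max_epochs >= 1, patience >= 1,
            batch_size >= 1, folds >= 1,
            train_fraction > 0, train_fraction < 1)
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 max_epochs = max_epochs, patience = patience,
                 batch_size = batch_size, folds = folds,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "training_protocol")
}

#' Contiguous shifting-origin fold partitions
#'
#' Fold `f` validates on a contiguous block of `(1 - train_fraction)` of the
#' windows whose origin shifts by `1/folds` of the series per fold (wrapping
#' around the end), and trains on the rest; temporal order is preserved
#' within both parts and across the folds every window is used for both
#' training and validation.
#'
#' @param n Number of windows.
#' @param folds Number of folds.
#' @param train_fraction Training share per fold.
#' @return List of `folds` lists with integer `train` and `val` indices.
#' @export
fold_partition <- function(n, folds = 10, train_fraction = 0.8) {
  val_len <- max(1L, round((1 - train_fraction) * n))
  lapply(seq_len(folds) - 1L, function(f) {
    start <- floor(f * n / folds)
    val <- ((start + seq_len(val_len) - 1L) %% n) + 1L
    list(train = setdiff(seq_len(n), val), val = sort(val))
  })
}

#' Train one model on a windowed dataset
#'
#' Fits the spec's network(s) on the training windows under the uniform
#' protocol. For the composite stacked model the six base learners are
#' fitted at their own targets (30- and 60-minute) and the meta-learner is a
#' PLSR from base outputs to the requested horizon's target; for ensembles
#' each member is fitted independently.
#'
#' @param spec_id One of [zoo_spec_ids()], or a built model.
#' @param train_ds,val_ds Windowed datasets ([make_windows()] /
#'   [windows_subset()]) for fitting and validation.
#' @param horizon Prediction horizon in minutes (must be present in the
#'   datasets' targets).
#' @param protocol A [training_protocol()].
#' @return A `glybench_fit`: the trained model, its training history and
#'   metadata.
#' @export
train_model <- function(spec_id, train_ds, val_ds, horizon = 30,
                        protocol = training_protocol()) {
  model <- if (is.character(spec_id)) {
    build_model(spec_id, input_steps = dim(train_ds$inputs)[2],
                n_features = dim(train_ds$inputs)[3], seed = protocol$seed)
  } else spec_id
  h <- as.character(horizon)
  if (!h %in% names(train_ds$targets)) {
    stop("horizon ", horizon, " not present in the windowed dataset",
         call. = FALSE)
  }
  fit <- train_model_impl(model, train_ds, val_ds, h, protocol)
  structure(list(model = fit$model, history = fit$history,
                 spec_id = spec_label(model), horizon = horizon,
                 protocol = protocol,
                 scale_stats = train_ds$scale_stats,
                 bg_minmax = train_ds$bg_minmax),
            class = "glybench_fit")
}

spec_label <- function(model) {
  if (inherits(model, "nn_graph")) model$spec_id
  else model$spec_id
}

train_model_impl <- function(model, train_ds, val_ds, h, protocol) {
  UseMethod("train_model_impl")
}

#' @export
train_model_impl.nn_graph <- function(model, train_ds, val_ds, h, protocol) {
  fit <- fit_graph(model, train_ds$inputs, train_ds$targets[[h]],
                   val_ds$inputs, val_ds$targets[[h]], protocol,
                   scale_stats = train_ds$scale_stats,
                   bg_minmax = train_ds$bg_minmax)
  list(model = fit$graph, history = fit$history)
}

#' @export
train_model_impl.glybench_ensemble <- function(model, train_ds, val_ds, h,
                                               protocol) {
  histories <- list()
  for (m in names(model$members)) {
    fit <- train_model_impl(model$members[[m]], train_ds, val_ds, h, protocol)
    model$members[[m]] <- fit$model
    histories[[m]] <- dplyr::mutate(fit$history, member = m)
  }
  list(model = model, history = dplyr::bind_rows(histories))
}

#' @export
train_model_impl.glybench_composite <- function(model, train_ds, val_ds, h,
                                                protocol) {
  histories <- list()
  for (bn in names(model$base)) {
    b <- model$base[[bn]]
    bh <- as.character(b$horizon)
    if (!bh %in% names(train_ds$targets)) {
      stop("composite base learner needs horizon ", bh,
           " in the windowed dataset", call. = FALSE)
    }
    if (b$type == "plsr") {
      Xf <- matrix(train_ds$inputs, nrow = dim(train_ds$inputs)[1])
      model$base[[bn]]$model <- plsr_fit(Xf, train_ds$targets[[bh]], ncomp = 2)
    } else {
      fit <- fit_graph(b$graph, train_ds$inputs, train_ds$targets[[bh]],
                       val_ds$inputs, val_ds$targets[[bh]], protocol,
                       scale_stats = train_ds$scale_stats,
                       bg_minmax = train_ds$bg_minmax)
      model$base[[bn]]$graph <- fit$graph
      histories[[bn]] <- dplyr::mutate(fit$history, member = bn)
    }
  }
  base_out <- composite_base_outputs(model, train_ds)
  model$meta <- plsr_fit(base_out, train_ds$targets[[h]], ncomp = 2)
  list(model = model, history = dplyr::bind_rows(histories))
}

composite_base_outputs <- function(model, ds) {
  cols <- lapply(model$base, function(b) {
    if (b$type == "plsr") {
      plsr_predict(b$model, matrix(ds$inputs, nrow = dim(ds$inputs)[1]))
    } else {
      predict_raw(b$graph, ds$inputs)[, 1]
    }
  })
  do.call(cbind, cols)
}

#' Predict glucose (mg/dL) from a trained model
#'
#' Runs the model on a windowed dataset, rescales the network output to
#' mg/dL and clips it to the CGM range \[40, 400\].
#'
#' @param object A `glybench_fit`.
#' @param ds A `windowed_dataset`.
#' @param ... Unused.
#' @return Numeric vector of clipped predictions, one per window.
#' @export
predict.glybench_fit <- function(object, ds, ...) {
  model_predict(object$model, ds, object$scale_stats, object$bg_minmax)
}

model_predict <- function(model, ds, scale_stats, bg_minmax) {
  UseMethod("model_predict")
}

#' @export
model_predict.nn_graph <- function(model, ds, scale_stats, bg_minmax) {
  out <- predict_raw(model, ds$inputs)
  decode_predictions(model, out, scale_stats, bg_minmax)
}

#' @export
model_predict.glybench_ensemble <- function(model, ds, scale_stats, bg_minmax) {
  preds <- lapply(model$members, model_predict, ds = ds,
                  scale_stats = scale_stats, bg_minmax = bg_minmax)
  ensemble_predict(preds)
}

#' @export
model_predict.glybench_composite <- function(model, ds, scale_stats, bg_minmax) {
  base_out <- composite_base_outputs(model, ds)
  v <- plsr_predict(model$meta, base_out)
  clip_predictions(unscale_bg(v, scale_stats, bg_minmax), model_id = "khadem")
}

#' Naive last-value-carried-forward forecast
#'
#' Predicts that glucose `horizon` minutes ahead equals the window's last
#' observed value; the floor any learned forecaster must beat.
#'
#' @param ds A `windowed_dataset`.
#' @return Clipped mg/dL predictions, one per window.
#' @export
naive_forecast <- function(ds) {
  last_bg <- ds$inputs[, dim(ds$inputs)[2], 1]
  clip_predictions(unscale_bg(last_bg, ds$scale_stats, ds$bg_minmax))
}

#' Actual glucose targets of a windowed dataset, in mg/dL
#'
#' @param ds A `windowed_dataset`.
#' @param horizon Horizon in minutes.
#' @return Numeric vector of targets (clipped to the CGM range).
#' @export
window_targets <- function(ds, horizon) {
  h <- as.character(horizon)
  clip_predictions(unscale_bg(ds$targets[[h]], ds$scale_stats, ds$bg_minmax))
}

#' Cross-validate a spec over a cohort
#'
#' For each patient: windows are built from the scaled, gap-free series; the
#' training partition's windows are split into `protocol$folds` contiguous
#' 80/20 train/validation folds (temporal order preserved); in each fold the
#' model is fitted and the held-out test partition is predicted once.
#' Predictions are rescaled and clipped before any metric.
#'
#' @param spec_id One of [zoo_spec_ids()].
#' @param cohort A gap-free `cgm_series` (one or more patients).
#' @param horizon Prediction horizon in minutes.
#' @param protocol A [training_protocol()].
#' @param horizons Horizons to window (must cover `horizon` and, for the
#'   composite model, 30 and 60).
#' @return A `glybench_cv` list: `predictions` (tibble patient, fold, time,
#'   actual, predicted), `metrics` (per patient x fold), `losses` (per
#'   patient x fold RMSE, the loss unit for model comparison).
#' @export
cross_validate <- function(spec_id, cohort, horizon = 30,
                           protocol = training_protocol(),
                           horizons = c(30, 60, 120)) {
  preds <- list()
  for (pid in unique(cohort$patient_id)) {
    series <- cohort[cohort$patient_id == pid, ]
    series <- new_cgm_series(series)
    scaled <- scale_features(series)
    ds <- make_windows(scaled, horizons = horizons)
    tr_idx <- which(ds$meta$partition == "train")
    te_idx <- which(ds$meta$partition == "test")
    if (length(tr_idx) == 0 || length(te_idx) == 0) {
      warning("patient ", pid, ": insufficient windows; skipped", call. = FALSE)
      next
    }
    train_all <- windows_subset(ds, tr_idx)
    test_ds <- windows_subset(ds, te_idx)
    parts <- fold_partition(length(tr_idx), protocol$folds,
                            protocol$train_fraction)
    for (f in seq_along(parts)) {
      n_tr <- length(parts[[f]]$train)
      if (n_tr < protocol$batch_size) {
        warning("patient ", pid, " fold ", f, ": too few windows; skipped",
                call. = FALSE)
        next
      }
      fold_protocol <- protocol
      fold_protocol$seed <- protocol$seed + 131L * f
      fit <- train_model(spec_id, windows_subset(train_all, parts[[f]]$train),
                         windows_subset(train_all, parts[[f]]$val),
                         horizon = horizon, protocol = fold_protocol)
      actual <- window_targets(test_ds, horizon)
      predicted <- predict(fit, test_ds)
      preds[[length(preds) + 1]] <- tibble::tibble(
        patient_id = pid, fold = f, model = spec_label(fit$model),
        horizon = horizon, time = test_ds$meta$time,
        actual = actual, predicted = predicted
      )
    }
  }
  predictions <- dplyr::bind_rows(preds)
  metrics <- dplyr::group_modify(
    dplyr::group_by(predictions, .data$patient_id, .data$fold, .data$model,
                    .data$horizon),
    function(d, key) compute_metrics(d)
  )
  metrics <- dplyr::ungroup(metrics)
  losses <- dplyr::select(metrics, "patient_id", "fold", "model", "horizon",
                          loss = "rmse")
  structure(list(predictions = predictions, metrics = metrics,
                 losses = losses),
            class = "glybench_cv")
}
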