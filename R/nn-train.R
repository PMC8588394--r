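# Adam optimizer and the mini-batch fit loop with early stopping.

adam_state_init <- function(graph) {
  st <- list()
  for (id in graph$order) {
    p <- graph$nodes[[id]]$layer$params
    if (length(p) == 0) next
    st[[id]] <- lapply(p, function(w) {
      list(m = array(0, dim = dim(w) %||% length(w)),
           v = array(0, dim = dim(w) %||% length(w)))
    })
  }
  st
}

adam_update <- function(graph, grads, state, step, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  b1t <- 1 - beta1^step
  b2t <- 1 - beta2^step
  for (id in names(grads)) {
    g_node <- grads[[id]]
    if (length(g_node) == 0) next
    for (pn in names(g_node)) {
      g <- g_node[[pn]]
      s <- state[[id]][[pn]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      state[[id]][[pn]] <- s
      upd <- lr * (s$m / b1t) / (sqrt(s$v / b2t) + eps)
      graph$nodes[[id]]$layer$params[[pn]] <-
        graph$nodes[[id]]$layer$params[[pn]] - upd
    }
  }
  list(graph = graph, state = state)
}

graph_params <- function(graph) {
  lapply(graph$nodes, function(nd) {
    list(params = nd$layer$params, state = nd$layer$state)
  })
}

graph_set_params <- function(graph, snapshot) {
  for (id in names(snapshot)) {
    graph$nodes[[id]]$layer$params <- snapshot[[id]]$params
    if (!is.null(snapshot[[id]]$state)) {
      graph$nodes[[id]]$layer$state <- snapshot[[id]]$state
    }
  }
  graph
}

# Supervised targets in the representation the graph's loss expects.
loss_target <- function(graph, y_scaled, scale_stats = NULL, bg_minmax = FALSE) {
  if (graph$loss == "categorical") {
    risk_encode(clip_predictions(unscale_bg(y_scaled, scale_stats, bg_minmax)))
  } else {
    y_scaled
  }
}

# One full fit: mini-batch Adam, early stopping on validation loss with
# best-epoch weight restoration. X (n, steps, feats); y scaled glucose.
fit_graph <- function(graph, X, y, X_val, y_val, protocol,
                      scale_stats = NULL, bg_minmax = FALSE) {
  rng <- local_rng(protocol$seed)
  on.exit(rng(), add = TRUE)
  n <- dim(X)[1]
  if (n < 1) stop("no training windows", call. = FALSE)
  target <- loss_target(graph, y, scale_stats, bg_minmax)
  target_val <- loss_target(graph, y_val, scale_stats, bg_minmax)
  state <- adam_state_init(graph)
  best <- list(val = Inf, snapshot = NULL, epoch = 0)
  history <- vector("list", protocol$max_epochs)
  step <- 0
  actual_tr <- clip_predictions(unscale_bg(y, scale_stats, bg_minmax))
  for (epoch in seq_len(protocol$max_epochs)) {
    idx <- sample.int(n)
    # training loss and MAE are running averages over the epoch's batches
    ep_loss <- 0; ep_mae <- 0; ep_n <- 0
    for (at in seq(1, n, by = protocol$batch_size)) {
      bi <- idx[at:min(n, at + protocol$batch_size - 1)]
      fc <- forward_graph(graph, X[bi, , , drop = FALSE], training = TRUE)
      graph <- fc$graph
      lb <- loss_forward_backward(graph$loss, as.matrix(fc$out), target[bi])
      grads <- backward_graph(graph, fc$caches, lb$dout)
      step <- step + 1
      au <- adam_update(graph, grads, state, step, protocol$learning_rate)
      graph <- au$graph; state <- au$state
      if (!is.finite(lb$loss)) {
        stop("training diverged (non-finite loss) for spec '", graph$spec_id,
             "'", call. = FALSE)
      }
      bpred <- decode_predictions(graph, as.matrix(fc$out), scale_stats,
                                  bg_minmax)
      ep_loss <- ep_loss + lb$loss * length(bi)
      ep_mae <- ep_mae + sum(abs(bpred - actual_tr[bi]))
      ep_n <- ep_n + length(bi)
    }
    ev_va <- evaluate_graph(graph, X_val, target_val, y_val, scale_stats,
                            bg_minmax)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, loss = ep_loss / ep_n, mae = ep_mae / ep_n,
      val_loss = ev_va$loss, val_mae = ev_va$mae
    )
    if (ev_va$loss < best$val - 1e-12) {
      best <- list(val = ev_va$loss, snapshot = graph_params(graph),
                   epoch = epoch)
    } else if (epoch - best$epoch >= protocol$patience) {
      break
    }
  }
  if (!is.null(best$snapshot)) graph <- graph_set_params(graph, best$snapshot)
  list(graph = graph,
       history = dplyr::bind_rows(history[!vapply(history, is.null, logical(1))]),
       best_epoch = best$epoch)
}

# loss and MAE (mg/dL) on a dataset, in inference mode
evaluate_graph <- function(graph, X, target, y_scaled, scale_stats, bg_minmax) {
  if (dim(X)[1] == 0) return(list(loss = NA_real_, mae = NA_real_))
  out <- predict_raw(graph, X)
  l <- loss_forward_backward(graph$loss, as.matrix(out), target)$loss
  pred <- decode_predictions(graph, out, scale_stats, bg_minmax)
  actual <- clip_predictions(unscale_bg(y_scaled, scale_stats, bg_minmax))
  list(loss = l, mae = mean(abs(pred - actual)))
}
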