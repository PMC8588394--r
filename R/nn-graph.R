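# Directed-acyclic model graphs over the layer primitives.
#
# A graph is a list of nodes in topological order. Input nodes select a
# (time, feature) slice of the raw window tensor; every other node applies a
# layer to the outputs of its parent nodes (a concat node takes several).

node_spec <- function(id, kind, inputs = NULL, ...) {
  list(id = id, kind = kind, inputs = inputs, cfg = list(...))
}

build_graph <- function(nodes, loss, decoder, spec_id,
                        input_steps = 25, n_features = 4, seed = NULL) {
  if (!is.null(seed)) {
    rng <- local_rng(seed)
    on.exit(rng(), add = TRUE)
  }
  shapes <- list()
  built <- list()
  for (nd in nodes) {
    if (nd$kind == "input") {
      ti <- nd$cfg$time %||% seq_len(input_steps)
      fi <- nd$cfg$feat %||% seq_len(n_features)
      if (max(ti) > input_steps || max(fi) > n_features) {
        stop("input wiring incompatible with a ", input_steps, "x", n_features,
             " window", call. = FALSE)
      }
      shapes[[nd$id]] <- c(length(ti), length(fi))
      built[[nd$id]] <- list(id = nd$id, kind = "input", inputs = NULL,
                             cfg = list(time = ti, feat = fi),
                             layer = list(kind = "input", params = list()))
      next
    }
    in_shape <- if (nd$kind == "concat") {
      vapply(nd$inputs, function(i) shapes[[i]][1], numeric(1))
    } else {
      shapes[[nd$inputs]]
    }
    layer <- init_layer(nd$kind, nd$cfg, in_shape)
    shapes[[nd$id]] <- layer$out_shape
    built[[nd$id]] <- list(id = nd$id, kind = nd$kind, inputs = nd$inputs,
                           cfg = nd$cfg, layer = layer)
  }
  structure(list(nodes = built, order = vapply(nodes, `[[`, "", "id"),
                 output_id = nodes[[length(nodes)]]$id,
                 loss = loss, decoder = decoder, spec_id = spec_id,
                 input_steps = input_steps, n_features = n_features),
            class = "nn_graph")
}

forward_graph <- function(graph, X, training = FALSE) {
  outs <- list()
  caches <- list()
  for (id in graph$order) {
    nd <- graph$nodes[[id]]
    if (nd$kind == "input") {
      outs[[id]] <- X[, nd$cfg$time, nd$cfg$feat, drop = FALSE]
      next
    }
    x_in <- if (nd$kind == "concat") outs[nd$inputs] else outs[[nd$inputs]]
    fc <- forward_layer(nd$layer, x_in, training = training)
    outs[[id]] <- fc$out
    caches[[id]] <- fc$cache
    if (nd$kind == "batchnorm" && training) {
      m <- 0.99
      nd$layer$state$mean <- m * nd$layer$state$mean +
        (1 - m) * fc$cache$batch_mean
      nd$layer$state$var <- m * nd$layer$state$var +
        (1 - m) * fc$cache$batch_var
      graph$nodes[[id]] <- nd
    }
  }
  list(out = outs[[graph$output_id]], caches = caches, graph = graph)
}

backward_graph <- function(graph, caches, dout) {
  douts <- list()
  douts[[graph$output_id]] <- dout
  grads <- list()
  for (id in rev(graph$order)) {
    nd <- graph$nodes[[id]]
    if (nd$kind == "input") next
    d <- douts[[id]]
    if (is.null(d)) next
    bk <- backward_layer(nd$layer, caches[[id]], d)
    grads[[id]] <- bk$grads
    parents <- nd$inputs
    dxs <- if (nd$kind == "concat") bk$dx else list(bk$dx)
    for (k in seq_along(parents)) {
      p <- parents[k]
      douts[[p]] <- if (is.null(douts[[p]])) dxs[[k]] else douts[[p]] + dxs[[k]]
    }
  }
  grads
}

#' Count the parameters of a built model
#'
#' Totals every weight, bias and normalization statistic (trainable and
#' non-trainable alike, matching how deep-learning frameworks report model
#' size) across the graph.
#'
#' @param model An `nn_graph`, composite or ensemble model object.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  UseMethod("count_parameters")
}

#' @export
count_parameters.nn_graph <- function(model) {
  total <- 0L
  for (nd in model$nodes) {
    total <- total + sum(vapply(nd$layer$params, length, integer(1)))
    if (!is.null(nd$layer$state)) {
      total <- total + sum(vapply(nd$layer$state, length, integer(1)))
    }
  }
  as.integer(total)
}

#' @export
print.nn_graph <- function(x, ...) {
  cat("<nn_graph '", x$spec_id, "'> ", length(x$nodes), " nodes, ",
      count_parameters(x), " parameters, loss: ", x$loss, "\n", sep = "")
  invisible(x)
}

# ---- loss heads -----------------------------------------------------------

# Each returns list(loss, dout) for a batch; `target` is the supervised
# target in the representation the loss expects (scaled glucose for mse and
# the Gaussian head, 0-based bin indices for the categorical head).
loss_forward_backward <- function(loss, out, target) {
  B <- nrow(out)
  switch(loss,
    mse = {
      r <- out[, 1] - target
      list(loss = mean(r^2),
           dout = matrix(2 * r / B, ncol = 1))
    },
    gaussian_nll = {
      mu <- out[, 1]
      s <- out[, 2]
      elu <- ifelse(s > 0, s, exp(s) - 1)
      sigma <- elu + 1 + 1e-6
      r <- target - mu
      l <- mean(0.5 * log(2 * pi * sigma^2) + r^2 / (2 * sigma^2))
      dmu <- -r / sigma^2 / B
      dsigma <- (1 / sigma - r^2 / sigma^3) / B
      ds <- dsigma * ifelse(s > 0, 1, elu + 1)
      list(loss = l, dout = cbind(dmu, ds))
    },
    categorical = {
      z <- out - apply(out, 1, max)
      ez <- exp(z)
      p <- ez / rowSums(ez)
      idx <- cbind(seq_len(B), target + 1L)
      l <- mean(-log(pmax(p[idx], 1e-12)))
      dout <- p / B
      dout[idx] <- dout[idx] - 1 / B
      list(loss = l, dout = dout)
    },
    stop("unknown loss: ", loss, call. = FALSE)
  )
}

#' Gaussian negative log-likelihood
#'
#' Mean over the batch of the negative log of the full normal density
#' (including the 1/2 log(2 pi sigma^2) term), the training loss of the
#' heteroscedastic two-head model.
#'
#' @param actual Observed values.
#' @param mu Predicted means.
#' @param sigma Predicted standard deviations (strictly positive).
#' @return Scalar loss.
#' @export
gaussian_nll <- function(actual, mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be strictly positive", call. = FALSE)
  mean(0.5 * log(2 * pi * sigma^2) + (actual - mu)^2 / (2 * sigma^2))
}

# ---- prediction -----------------------------------------------------------

predict_raw <- function(graph, X, batch_size = 512) {
  n <- dim(X)[1]
  outs <- NULL
  for (at in seq(1, n, by = batch_size)) {
    idx <- at:min(n, at + batch_size - 1)
    o <- forward_graph(graph, X[idx, , , drop = FALSE], training = FALSE)$out
    outs <- rbind(outs, o)
  }
  outs
}

# decode raw network output to clipped mg/dL
decode_predictions <- function(graph, out, scale_stats = NULL,
                               bg_minmax = FALSE) {
  v <- switch(graph$decoder,
    identity = unscale_bg(out[, 1], scale_stats, bg_minmax),
    mu = unscale_bg(out[, 1], scale_stats, bg_minmax),
    bins = risk_decode(max.col(out, ties.method = "first") - 1L),
    stop("unknown decoder: ", graph$decoder, call. = FALSE)
  )
  clip_predictions(v, model_id = graph$spec_id)
}
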