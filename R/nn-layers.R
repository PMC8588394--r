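# Batched layer primitives with manual backpropagation.
#
# Tensors are base-R arrays: sequences are (batch, time, features), flat
# activations are (batch, features) matrices. Every layer implements
#   init_layer(kind, cfg, in_shape)     -> layer (params initialized)
#   forward_layer(layer, x, training)   -> list(out, cache)
#   backward_layer(layer, cache, dout)  -> list(dx, grads)
# with `grads` mirroring the structure of `layer$params`. Weight matrices use
# Glorot-uniform initialization, recurrent matrices are orthogonal, and LSTM
# forget-gate biases start at 1.

activation_f <- function(name) {
  switch(name,
    linear = identity,
    relu = function(x) pmax(x, 0),
    tanh = tanh,
    sigmoid = function(x) 1 / (1 + exp(-x)),
    elu = function(x) ifelse(x > 0, x, exp(x) - 1),
    stop("unknown activation: ", name, call. = FALSE)
  )
}

# derivative expressed in terms of the activation's *output* y
activation_df <- function(name) {
  switch(name,
    linear = function(y) 1,
    relu = function(y) (y > 0) * 1,
    tanh = function(y) 1 - y^2,
    sigmoid = function(y) y * (1 - y),
    elu = function(y) ifelse(y > 0, 1, y + 1),
    stop("unknown activation: ", name, call. = FALSE)
  )
}

glorot_uniform <- function(fan_in, fan_out, dim = c(fan_in, fan_out)) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dim), -limit, limit), dim = dim)
}

orthogonal_init <- function(rows, cols) {
  a <- matrix(stats::rnorm(rows * cols), max(rows, cols), min(rows, cols))
  qr_a <- qr(a)
  q <- qr.Q(qr_a)
  q <- q * rep(sign(diag(qr.R(qr_a)) + 1e-300), each = nrow(q))
  if (rows >= cols) q[seq_len(rows), seq_len(cols), drop = FALSE]
  else t(q)[seq_len(rows), seq_len(cols), drop = FALSE]
}

slab <- function(x, t) {
  # time-slice of a (B, T, F) array as a (B, F) matrix
  matrix(x[, t, ], nrow = dim(x)[1])
}

init_layer <- function(kind, cfg, in_shape) {
  layer <- list(kind = kind, cfg = cfg, in_shape = in_shape)
  layer$params <- switch(kind,
    input = list(),
    flatten = list(),
    maxpool1d = list(),
    concat = list(),
    dense = {
      f_in <- in_shape[length(in_shape)]
      list(W = glorot_uniform(f_in, cfg$units), b = numeric(cfg$units))
    },
    conv1d = {
      f_in <- in_shape[2]
      list(W = glorot_uniform(cfg$kernel * f_in, cfg$filters,
                              dim = c(cfg$kernel, f_in, cfg$filters)),
           b = numeric(cfg$filters))
    },
    batchnorm = {
      f_in <- in_shape[length(in_shape)]
      list(gamma = rep(1, f_in), beta = numeric(f_in))
    },
    lstm = lstm_params(in_shape[2], cfg$units),
    bilstm = {
      p <- lstm_params(in_shape[2], cfg$units)
      names(p) <- paste0(names(p), "_f")
      pb <- lstm_params(in_shape[2], cfg$units)
      names(pb) <- paste0(names(pb), "_b")
      c(p, pb)
    },
    rnn = list(W = glorot_uniform(in_shape[2], cfg$units),
               U = orthogonal_init(cfg$units, cfg$units),
               b = numeric(cfg$units)),
    stop("unknown layer kind: ", kind, call. = FALSE)
  )
  if (kind == "batchnorm") {
    f_in <- in_shape[length(in_shape)]
    layer$state <- list(mean = numeric(f_in), var = rep(1, f_in))
  }
  layer$out_shape <- layer_out_shape(kind, cfg, in_shape)
  layer
}

lstm_params <- function(f_in, units) {
  b <- numeric(4 * units)
  b[(units + 1):(2 * units)] <- 1 # forget-gate bias starts open
  list(W = glorot_uniform(f_in, 4 * units),
       U = orthogonal_init(units, 4 * units),
       b = b)
}

layer_out_shape <- function(kind, cfg, in_shape) {
  switch(kind,
    input = in_shape,
    dense = c(cfg$units),
    conv1d = c(in_shape[1] - cfg$kernel + 1, cfg$filters),
    maxpool1d = c(floor(in_shape[1] / cfg$pool), in_shape[2]),
    flatten = c(prod(in_shape)),
    batchnorm = in_shape,
    lstm = if (isTRUE(cfg$return_seq)) c(in_shape[1], cfg$units) else c(cfg$units),
    bilstm = c(2 * cfg$units),
    rnn = if (isTRUE(cfg$return_seq)) c(in_shape[1], cfg$units) else c(cfg$units),
    concat = c(sum(in_shape))
  )
}

forward_layer <- function(layer, x, training = FALSE) {
  switch(layer$kind,
    dense = forward_dense(layer, x),
    conv1d = forward_conv1d(layer, x),
    maxpool1d = forward_maxpool(layer, x),
    flatten = list(out = matrix(x, nrow = dim(x)[1]), cache = dim(x)),
    batchnorm = forward_batchnorm(layer, x, training),
    lstm = forward_lstm(layer$params, layer$cfg, x, training = training),
    bilstm = forward_bilstm(layer, x, training = training),
    rnn = forward_rnn(layer, x, training = training),
    concat = list(out = do.call(cbind, x),
                  cache = vapply(x, ncol, integer(1))),
    stop("unknown layer kind: ", layer$kind, call. = FALSE)
  )
}

backward_layer <- function(layer, cache, dout) {
  switch(layer$kind,
    dense = backward_dense(layer, cache, dout),
    conv1d = backward_conv1d(layer, cache, dout),
    maxpool1d = backward_maxpool(layer, cache, dout),
    flatten = list(dx = array(dout, dim = cache), grads = list()),
    batchnorm = backward_batchnorm(layer, cache, dout),
    lstm = backward_lstm(layer$params, layer$cfg, cache, dout),
    bilstm = backward_bilstm(layer, cache, dout),
    rnn = backward_rnn(layer, cache, dout),
    concat = {
      splits <- cache
      at <- 0
      dx <- lapply(splits, function(k) {
        d <- dout[, at + seq_len(k), drop = FALSE]
        at <<- at + k
        d
      })
      list(dx = dx, grads = list())
    },
    stop("unknown layer kind: ", layer$kind, call. = FALSE)
  )
}

forward_dense <- function(layer, x) {
  act <- activation_f(layer$cfg$activation)
  z <- x %*% layer$params$W
  z <- z + rep(layer$params$b, each = nrow(x))
  y <- act(z)
  list(out = y, cache = list(x = x, y = y))
}

backward_dense <- function(layer, cache, dout) {
  df <- activation_df(layer$cfg$activation)
  dz <- dout * df(cache$y)
  list(dx = dz %*% t(layer$params$W),
       grads = list(W = t(cache$x) %*% dz, b = colSums(dz)))
}

forward_conv1d <- function(layer, x) {
  k <- layer$cfg$kernel
  B <- dim(x)[1]; T_in <- dim(x)[2]
  T_out <- T_in - k + 1
  M <- layer$cfg$filters
  z <- array(rep(layer$params$b, each = B * T_out), dim = c(B, T_out, M))
  for (j in seq_len(k)) {
    Wj <- matrix(layer$params$W[j, , ], nrow = dim(x)[3])
    for (t in seq_len(T_out)) {
      z[, t, ] <- matrix(z[, t, ], nrow = B) + slab(x, t + j - 1) %*% Wj
    }
  }
  y <- activation_f(layer$cfg$activation)(z)
  list(out = y, cache = list(x = x, y = y))
}

backward_conv1d <- function(layer, cache, dout) {
  k <- layer$cfg$kernel
  x <- cache$x
  B <- dim(x)[1]; T_out <- dim(dout)[2]
  dz <- dout * activation_df(layer$cfg$activation)(cache$y)
  dW <- array(0, dim = dim(layer$params$W))
  dx <- array(0, dim = dim(x))
  for (j in seq_len(k)) {
    Wj <- matrix(layer$params$W[j, , ], nrow = dim(x)[3])
    dWj <- matrix(0, dim(x)[3], layer$cfg$filters)
    for (t in seq_len(T_out)) {
      dzt <- matrix(dz[, t, ], nrow = B)
      dWj <- dWj + t(slab(x, t + j - 1)) %*% dzt
      dx[, t + j - 1, ] <- matrix(dx[, t + j - 1, ], nrow = B) + dzt %*% t(Wj)
    }
    dW[j, , ] <- dWj
  }
  list(dx = dx, grads = list(W = dW, b = apply(dz, 3, sum)))
}

forward_maxpool <- function(layer, x) {
  p <- layer$cfg$pool
  B <- dim(x)[1]; T_out <- floor(dim(x)[2] / p); F_in <- dim(x)[3]
  out <- array(-Inf, dim = c(B, T_out, F_in))
  amax <- array(1L, dim = c(B, T_out, F_in))
  for (j in seq_len(p)) {
    for (t in seq_len(T_out)) {
      cand <- matrix(x[, (t - 1) * p + j, ], nrow = B)
      cur <- matrix(out[, t, ], nrow = B)
      better <- cand > cur
      out[, t, ][better] <- cand[better]
      amax[, t, ][better] <- j
    }
  }
  list(out = out, cache = list(amax = amax, in_dim = dim(x)))
}

backward_maxpool <- function(layer, cache, dout) {
  p <- layer$cfg$pool
  dx <- array(0, dim = cache$in_dim)
  B <- cache$in_dim[1]
  for (t in seq_len(dim(dout)[2])) {
    for (j in seq_len(p)) {
      sel <- matrix(cache$amax[, t, ], nrow = B) == j
      d <- matrix(dout[, t, ], nrow = B) * sel
      dx[, (t - 1) * p + j, ] <- matrix(dx[, (t - 1) * p + j, ], nrow = B) + d
    }
  }
  list(dx = dx, grads = list())
}

forward_batchnorm <- function(layer, x, training) {
  eps <- 1e-3
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu)^2)
  } else {
    mu <- layer$state$mean
    v <- layer$state$var
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x, 2, mu), 2, inv_std, `*`)
  y <- sweep(sweep(xhat, 2, layer$params$gamma, `*`), 2, layer$params$beta, `+`)
  list(out = y,
       cache = list(xhat = xhat, inv_std = inv_std, training = training,
                    batch_mean = mu, batch_var = v))
}

backward_batchnorm <- function(layer, cache, dout) {
  B <- nrow(dout)
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  g_inv <- layer$params$gamma * cache$inv_std
  if (cache$training) {
    dx <- sweep(B * dout - rep(dbeta, each = B) - xhat * rep(dgamma, each = B),
                2, g_inv / B, `*`)
  } else {
    dx <- sweep(dout, 2, g_inv, `*`)
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# Recurrent cells run on the compiled kernels; sequences cross the boundary
# as (batch, features, time) so each step is a contiguous matrix.
seq_to_bft <- function(x) aperm(x, c(1, 3, 2))
bft_to_seq <- function(x) aperm(x, c(1, 3, 2))

forward_lstm <- function(params, cfg, x, suffix = "", training = TRUE) {
  relu <- identical(cfg$activation, "relu")
  seq_out <- isTRUE(cfg$return_seq)
  xp <- seq_to_bft(x)
  W <- params[[paste0("W", suffix)]]
  U <- params[[paste0("U", suffix)]]
  b <- params[[paste0("b", suffix)]]
  if (!training) { # cache-free inference path
    res <- .lstm_infer_cpp(xp, W, U, b, relu, seq_out)
    out <- if (seq_out) bft_to_seq(res$Hs) else res$out_last
    return(list(out = out, cache = NULL))
  }
  res <- .lstm_forward_cpp(xp, W, U, b, relu, seq_out)
  out <- if (seq_out) bft_to_seq(res$Hs) else res$out_last
  res$out_last <- NULL
  res$xp <- xp
  list(out = out, cache = res)
}

backward_lstm <- function(params, cfg, cache, dout, suffix = "") {
  relu <- identical(cfg$activation, "relu")
  seq_out <- isTRUE(cfg$return_seq)
  B <- dim(cache$xp)[1]; H <- dim(cache$Hs)[2]
  dout_seq <- if (seq_out) seq_to_bft(dout) else array(0, dim = c(1, 1, 1))
  dout_last <- if (seq_out) matrix(0, 1, 1) else dout
  res <- .lstm_backward_cpp(cache$xp, params[[paste0("W", suffix)]],
                            params[[paste0("U", suffix)]],
                            cache$I, cache$Fg, cache$G, cache$O, cache$C,
                            cache$Hc, cache$Hs, dout_seq, dout_last, relu,
                            seq_out)
  grads <- list(res$dW, res$dU, drop(res$db))
  names(grads) <- paste0(c("W", "U", "b"), suffix)
  list(dx = bft_to_seq(res$dx), grads = grads)
}

forward_bilstm <- function(layer, x, training = TRUE) {
  fwd <- forward_lstm(layer$params, c(layer$cfg, return_seq = FALSE), x,
                      suffix = "_f", training = training)
  xr <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  bwd <- forward_lstm(layer$params, c(layer$cfg, return_seq = FALSE), xr,
                      suffix = "_b", training = training)
  list(out = cbind(fwd$out, bwd$out),
       cache = list(fwd = fwd$cache, bwd = bwd$cache))
}

backward_bilstm <- function(layer, cache, dout) {
  H <- layer$cfg$units
  cfg <- c(layer$cfg, return_seq = FALSE)
  bf <- backward_lstm(layer$params, cfg, cache$fwd,
                      dout[, seq_len(H), drop = FALSE], suffix = "_f")
  bb <- backward_lstm(layer$params, cfg, cache$bwd,
                      dout[, H + seq_len(H), drop = FALSE], suffix = "_b")
  dx <- bf$dx + bb$dx[, rev(seq_len(dim(bb$dx)[2])), , drop = FALSE]
  list(dx = dx, grads = c(bf$grads, bb$grads))
}

forward_rnn <- function(layer, x, training = TRUE) {
  cfg <- layer$cfg
  seq_out <- isTRUE(cfg$return_seq)
  xp <- seq_to_bft(x)
  d <- as.integer(cfg$dilation %||% 1)
  if (!training) {
    res <- .rnn_infer_cpp(xp, layer$params$W, layer$params$U, layer$params$b,
                          d, seq_out)
    out <- if (seq_out) bft_to_seq(res$Hs) else res$out_last
    return(list(out = out, cache = NULL))
  }
  res <- .rnn_forward_cpp(xp, layer$params$W, layer$params$U, layer$params$b,
                          d, seq_out)
  out <- if (seq_out) bft_to_seq(res$Hs) else res$out_last
  list(out = out, cache = list(xp = xp, Hs = res$Hs))
}

backward_rnn <- function(layer, cache, dout) {
  cfg <- layer$cfg
  seq_out <- isTRUE(cfg$return_seq)
  dout_seq <- if (seq_out) seq_to_bft(dout) else array(0, dim = c(1, 1, 1))
  dout_last <- if (seq_out) matrix(0, 1, 1) else dout
  res <- .rnn_backward_cpp(cache$xp, layer$params$W, layer$params$U,
                           cache$Hs, dout_seq, dout_last,
                           as.integer(cfg$dilation %||% 1), seq_out)
  list(dx = bft_to_seq(res$dx),
       grads = list(W = res$dW, U = res$dU, b = drop(res$db)))
}
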