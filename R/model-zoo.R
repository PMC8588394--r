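# Catalog of the benchmarked architectures.
#
# Ten published glucose forecasters plus two averaging ensembles. Each
# catalog entry is a declarative node list consumed by build_graph(); layer
# sizes, activations and wiring follow the published per-layer tables, and
# the parameter audit in the test suite checks the built models against the
# printed totals. Feature channels are ordered (bg, bas, bol, ch).

#' Model identifiers in the benchmark catalog
#'
#' @return Character vector of spec ids, the ten single networks followed by
#'   the two ensembles.
#' @export
zoo_spec_ids <- function() {
  c("mirshekarian", "meijner", "gulesir", "sun", "idriss", "aiello",
    "zhu", "mayo", "munoz", "khadem", "ensemble_mms", "ensemble_mmsz")
}

#' Members of the averaging ensembles
#'
#' MMS averages the Mirshekarian, Meijner and Sun networks; MMSZ adds Zhu.
#'
#' @param spec_id `"ensemble_mms"` or `"ensemble_mmsz"`.
#' @return Character vector of member spec ids.
#' @export
ensemble_members <- function(spec_id) {
  switch(spec_id,
    ensemble_mms = c("mirshekarian", "meijner", "sun"),
    ensemble_mmsz = c("mirshekarian", "meijner", "sun", "zhu"),
    stop("not an ensemble spec: ", spec_id, call. = FALSE)
  )
}

zoo_catalog <- function(spec_id, input_steps = 25, n_features = 4) {
  N <- node_spec
  switch(spec_id,
    mirshekarian = list(
      loss = "mse", decoder = "identity",
      nodes = list(
        N("in", "input"),
        N("lstm1", "lstm", "in", units = 5, activation = "tanh",
          return_seq = FALSE),
        N("out", "dense", "lstm1", units = 1, activation = "linear")
      )
    ),
    meijner = list(
      loss = "gaussian_nll", decoder = "mu",
      nodes = list(
        N("in", "input"),
        N("lstm1", "lstm", "in", units = 4, activation = "tanh",
          return_seq = FALSE),
        N("mu", "dense", "lstm1", units = 1, activation = "linear"),
        N("sd", "dense", "lstm1", units = 1, activation = "linear"),
        N("out", "concat", c("mu", "sd"))
      )
    ),
    gulesir = list(
      loss = "mse", decoder = "identity",
      nodes = list(
        N("in", "input"),
        N("conv1", "conv1d", "in", filters = 4, kernel = 5,
          activation = "relu"),
        N("pool1", "maxpool1d", "conv1", pool = 2),
        N("conv2", "conv1d", "pool1", filters = 4, kernel = 5,
          activation = "relu"),
        N("pool2", "maxpool1d", "conv2", pool = 2),
        N("flat", "flatten", "pool2"),
        N("out", "dense", "flat", units = 1, activation = "linear")
      )
    ),
    sun = list(
      loss = "mse", decoder = "identity",
      nodes = list(
        N("in", "input"),
        N("lstm1", "lstm", "in", units = 4, activation = "tanh",
          return_seq = TRUE),
        N("bilstm", "bilstm", "lstm1", units = 4, activation = "tanh"),
        N("d1", "dense", "bilstm", units = 4, activation = "linear"),
        N("d2", "dense", "d1", units = 64, activation = "linear"),
        N("d3", "dense", "d2", units = 4, activation = "linear"),
        N("out", "dense", "d3", units = 1, activation = "linear")
      )
    ),
    idriss = list(
      loss = "mse", decoder = "identity",
      nodes = list(
        N("in", "input"),
        N("lstm1", "lstm", "in", units = 50, activation = "tanh",
          return_seq = FALSE),
        N("d1", "dense", "lstm1", units = 30, activation = "sigmoid"),
        N("d2", "dense", "d1", units = 30, activation = "sigmoid"),
        N("out", "dense", "d2", units = 1, activation = "linear")
      )
    ),
    aiello = list(
      loss = "mse", decoder = "identity",
      nodes = list(
        N("in_hist", "input"),
        N("in_fut", "input",
          time = (input_steps - 5):input_steps, feat = 2:4),
        N("l1a", "lstm", "in_hist", units = 64, activation = "tanh",
          return_seq = TRUE),
        N("l2a", "lstm", "l1a", units = 64, activation = "tanh",
          return_seq = FALSE),
        N("l1b", "lstm", "in_fut", units = 64, activation = "tanh",
          return_seq = TRUE),
        N("l2b", "lstm", "l1b", units = 64, activation = "tanh",
          return_seq = FALSE),
        N("cat", "concat", c("l2a", "l2b")),
        N("out", "dense", "cat", units = 1, activation = "linear")
      )
    ),
    zhu = list(
      loss = "mse", decoder = "identity",
      nodes = list(
        N("in", "input"),
        N("r1", "rnn", "in", units = 32, activation = "tanh", dilation = 1,
          return_seq = TRUE),
        N("r2", "rnn", "r1", units = 32, activation = "tanh", dilation = 2,
          return_seq = TRUE),
        N("r3", "rnn", "r2", units = 32, activation = "tanh", dilation = 4,
          return_seq = FALSE),
        N("out", "dense", "r3", units = 1, activation = "linear")
      )
    ),
    mayo = list(
      loss = "categorical", decoder = "bins",
      nodes = list(
        N("in", "input"),
        N("lstm1", "lstm", "in", units = 12, activation = "tanh",
          return_seq = TRUE),
        N("flat", "flatten", "lstm1"),
        N("bn1", "batchnorm", "flat"),
        N("d1", "dense", "bn1", units = 50, activation = "relu"),
        N("bn2", "batchnorm", "d1"),
        N("out", "dense", "bn2", units = 100, activation = "linear")
      )
    ),
    munoz = {
      branch <- function(tag, feat) {
        list(
          N(paste0("in_", tag), "input", feat = feat),
          N(paste0("lstm_", tag), "lstm", paste0("in_", tag), units = 10,
            activation = "relu", return_seq = FALSE),
          N(paste0("d_", tag), "dense", paste0("lstm_", tag), units = 3,
            activation = "relu")
        )
      }
      list(
        loss = "mse", decoder = "identity",
        nodes = c(
          branch("bg", 1), branch("bas", 2), branch("bol", 3), branch("ch", 4),
          list(
            N("cat_nobg", "concat", c("d_bas", "d_bol", "d_ch")),
            N("mid", "dense", "cat_nobg", units = 1, activation = "linear"),
            N("cat_all", "concat", c("d_bg", "mid")),
            N("out", "dense", "cat_all", units = 1, activation = "linear")
          )
        )
      )
    },
    stop("unknown spec_id: ", spec_id, call. = FALSE)
  )
}

#' Build a model from the catalog
#'
#' Constructs a trainable model for one of the twelve catalog entries on a
#' `input_steps` x `n_features` window. Single networks become layer graphs;
#' `"khadem"` becomes a composite of six base learners (dense, LSTM and
#' partial-least-squares regressors at the 30- and 60-minute targets) under a
#' PLSR meta-learner, and the two `"ensemble_*"` ids become arithmetic-mean
#' ensembles over their member networks.
#'
#' @param spec_id One of [zoo_spec_ids()].
#' @param input_steps,n_features Input window shape.
#' @param seed Integer seed for weight initialization.
#' @return An `nn_graph`, `glybench_composite` or `glybench_ensemble`.
#' @export
build_model <- function(spec_id, input_steps = 25, n_features = 4, seed = 1L) {
  if (!spec_id %in% zoo_spec_ids()) {
    stop("unknown spec_id: ", spec_id, call. = FALSE)
  }
  if (spec_id == "khadem") {
    return(build_khadem(input_steps, n_features, seed))
  }
  if (startsWith(spec_id, "ensemble_")) {
    members <- lapply(seq_along(ensemble_members(spec_id)), function(i) {
      build_model(ensemble_members(spec_id)[i], input_steps, n_features,
                  seed = seed + i)
    })
    names(members) <- ensemble_members(spec_id)
    return(structure(list(spec_id = spec_id, members = members),
                     class = "glybench_ensemble"))
  }
  cat_entry <- zoo_catalog(spec_id, input_steps, n_features)
  build_graph(cat_entry$nodes, cat_entry$loss, cat_entry$decoder, spec_id,
              input_steps = input_steps, n_features = n_features, seed = seed)
}

# Khadem-style stacked generalization: six base learners (one dense NN, one
# LSTM NN and one PLSR at each of the 30- and 60-minute targets) whose
# outputs feed a PLSR meta-learner predicting the requested horizon.
build_khadem <- function(input_steps = 25, n_features = 4, seed = 1L) {
  base_graph <- function(type, tag, s) {
    nodes <- if (type == "dense") {
      list(
        node_spec("in", "input"),
        node_spec("flat", "flatten", "in"),
        node_spec("d1", "dense", "flat", units = 100, activation = "relu"),
        node_spec("out", "dense", "d1", units = 1, activation = "relu")
      )
    } else {
      list(
        node_spec("in", "input"),
        node_spec("lstm1", "lstm", "in", units = 200, activation = "relu",
                  return_seq = FALSE),
        node_spec("d1", "dense", "lstm1", units = 100, activation = "relu"),
        node_spec("out", "dense", "d1", units = 1, activation = "relu")
      )
    }
    build_graph(nodes, "mse", "identity", paste0("khadem_", type, "_", tag),
                input_steps = input_steps, n_features = n_features, seed = s)
  }
  base <- list()
  s <- seed
  for (h in c(30, 60)) {
    tag <- as.character(h)
    base[[paste0("dense_", tag)]] <-
      list(type = "dense", horizon = h, graph = base_graph("dense", tag, s <- s + 1))
    base[[paste0("lstm_", tag)]] <-
      list(type = "lstm", horizon = h, graph = base_graph("lstm", tag, s <- s + 1))
    base[[paste0("plsr_", tag)]] <-
      list(type = "plsr", horizon = h, model = NULL)
  }
  structure(list(spec_id = "khadem", base = base, meta = NULL,
                 input_steps = input_steps, n_features = n_features),
            class = "glybench_composite")
}

#' @export
count_parameters.glybench_composite <- function(model) {
  nn <- sum(vapply(model$base, function(b) {
    if (!is.null(b$graph)) count_parameters(b$graph) else 0L
  }, integer(1)))
  as.integer(nn)
}

#' @export
count_parameters.glybench_ensemble <- function(model) {
  as.integer(sum(vapply(model$members, count_parameters, integer(1))))
}

#' @export
print.glybench_composite <- function(x, ...) {
  cat("<glybench_composite 'khadem'> 6 base learners + PLSR meta-learner, ",
      count_parameters(x), " network parameters\n", sep = "")
  invisible(x)
}

#' @export
print.glybench_ensemble <- function(x, ...) {
  cat("<glybench_ensemble '", x$spec_id, "'> members: ",
      paste(names(x$members), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Audit built models against the published parameter counts
#'
#' @return A tibble with, per architecture, the parameter count of the built
#'   model and the count printed in the source publication (NA where the
#'   publication's count is not reproducible from the printed table alone).
#' @export
audit_parameters <- function() {
  printed <- c(mirshekarian = 206, meijner = 154, gulesir = 181, sun = 1053,
               idriss = 13491, aiello = 101249, zhu = 5377, mayo = 22366,
               munoz = NA, khadem = NA)
  tibble::tibble(
    spec_id = names(printed),
    built = unname(vapply(names(printed),
                          function(s) count_parameters(build_model(s)),
                          integer(1))),
    printed = unname(printed)
  )
}

# ---- risk-domain transform ------------------------------------------------

# Monotone logarithmic symmetrization of the glucose scale, calibrated so
# that 40 mg/dL maps to -2 and 400 mg/dL to +2; the classification model
# discretizes this [-2, 2] range into 100 equal bins.
risk_constants <- function() {
  alpha <- 1.084
  a40 <- log(40)^alpha
  a400 <- log(400)^alpha
  list(alpha = alpha, beta = (a40 + a400) / 2, gamma = 4 / (a400 - a40))
}

risk_transform <- function(bg) {
  k <- risk_constants()
  k$gamma * (log(bg)^k$alpha - k$beta)
}

risk_inverse <- function(r) {
  k <- risk_constants()
  exp((r / k$gamma + k$beta)^(1 / k$alpha))
}

#' Encode glucose as a risk-domain class bin
#'
#' Maps glucose through the monotone risk transform onto \[-2, 2\] and
#' returns the containing bin among 100 equally spaced bins (0-based).
#'
#' @param bg Glucose in mg/dL, inside \[40, 400\].
#' @return Integer bin indices in 0..99.
#' @export
risk_encode <- function(bg) {
  if (any(bg < 40 - 1e-9 | bg > 400 + 1e-9)) {
    stop("bg outside [40, 400] mg/dL", call. = FALSE)
  }
  r <- risk_transform(bg)
  pmin(99L, pmax(0L, as.integer(floor((r + 2) / 0.04))))
}

#' Decode a risk bin back to glucose
#'
#' @param bin Integer bin indices in 0..99.
#' @return The glucose value (mg/dL) of each bin's center.
#' @export
risk_decode <- function(bin) {
  if (any(bin < 0 | bin > 99)) stop("bin outside 0..99", call. = FALSE)
  risk_inverse(-2 + 0.04 * (bin + 0.5))
}

# ---- ensembles ------------------------------------------------------------

#' Average member predictions into an ensemble prediction
#'
#' The ensemble outcome is the element-wise arithmetic mean of the member
#' model outcomes (equal-weight Bayesian voting), clipped to the CGM range.
#'
#' @param member_predictions List of at least two aligned mg/dL vectors.
#' @return Clipped mg/dL vector.
#' @export
ensemble_predict <- function(member_predictions) {
  if (length(member_predictions) < 2) {
    stop("an ensemble needs at least two member predictions", call. = FALSE)
  }
  n <- unique(vapply(member_predictions, length, integer(1)))
  if (length(n) != 1) {
    stop("member predictions are not aligned (length mismatch)", call. = FALSE)
  }
  clip_predictions(rowMeans(do.call(cbind, member_predictions)),
                   model_id = "ensemble")
}

# ---- partial least squares -----------------------------------------------

# Minimal SIMPLS partial-least-squares regression (de Jong 1993) for the
# stacked-generalization learners: X (n x p), y (n), ncomp components.
plsr_fit <- function(X, y, ncomp = 2) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, p, n - 1)
  mx <- colMeans(X); my <- mean(y)
  Xc <- sweep(X, 2, mx)
  yc <- y - my
  S <- crossprod(Xc, yc)
  R <- matrix(0, p, ncomp)
  V <- matrix(0, p, ncomp)
  for (a in seq_len(ncomp)) {
    r <- S
    t_sc <- Xc %*% r
    t_sd <- sqrt(sum(t_sc^2))
    if (t_sd < 1e-12) { ncomp <- a - 1; break }
    r <- r / t_sd; t_sc <- t_sc / t_sd
    pvec <- crossprod(Xc, t_sc)
    v <- pvec
    if (a > 1) {
      Va <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Va %*% crossprod(Va, pvec)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r
    V[, a] <- v
  }
  if (ncomp == 0) {
    coefs <- matrix(0, p, 1)
  } else {
    R <- R[, seq_len(ncomp), drop = FALSE]
    T_sc <- Xc %*% R
    q <- crossprod(T_sc, yc)
    coefs <- R %*% q
  }
  structure(list(coef = coefs, x_mean = mx, y_mean = my), class = "glybench_plsr")
}

plsr_predict <- function(model, X) {
  drop(sweep(as.matrix(X), 2, model$x_mean) %*% model$coef) + model$y_mean
}
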