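# Loss-based model comparison: Bayesian Plackett-Luce ranking, the Model
# Confidence Set (Hansen, Lunde & Nason 2011, T_max statistic) and the
# Superior Predictive Ability test (Hansen 2005), all on an observations x
# models loss matrix (here: per-fold-per-patient RMSE).

#' Assemble a loss matrix from tidy per-unit losses
#'
#' @param losses A tibble with columns `model`, `loss` and unit identifiers
#'   (e.g. `patient_id`, `fold`), as produced by [cross_validate()].
#' @return A numeric observations x models matrix with models as columns,
#'   carrying the horizon tag as attribute when a `horizon` column is
#'   present.
#' @export
loss_matrix <- function(losses) {
  unit_cols <- setdiff(names(losses), c("model", "loss", "horizon"))
  wide <- tidyr::pivot_wider(
    losses[c(unit_cols, "model", "loss")],
    names_from = "model", values_from = "loss"
  )
  m <- as.matrix(wide[setdiff(names(wide), unit_cols)])
  if (anyNA(m)) stop("loss matrix has missing cells", call. = FALSE)
  if ("horizon" %in% names(losses)) {
    attr(m, "horizon") <- paste(sort(unique(losses$horizon)), collapse = "+")
  }
  m
}

check_losses <- function(losses, min_models = 2) {
  losses <- as.matrix(losses)
  if (is.null(colnames(losses))) {
    colnames(losses) <- paste0("model", seq_len(ncol(losses)))
  }
  if (ncol(losses) < min_models) {
    stop("need at least ", min_models, " models", call. = FALSE)
  }
  if (anyNA(losses) || any(losses < 0)) {
    stop("losses must be complete and non-negative", call. = FALSE)
  }
  losses
}

#' Combine per-horizon loss matrices into a multi-horizon matrix
#'
#' Row-wise concatenation of two loss matrices over the same model set,
#' giving the joint multi-horizon evaluation unit.
#'
#' @param losses_a,losses_b Observations x models matrices with identical
#'   column sets.
#' @return The stacked matrix, tagged with the combined horizon.
#' @export
multi_horizon <- function(losses_a, losses_b) {
  losses_a <- check_losses(losses_a)
  losses_b <- check_losses(losses_b)
  if (!setequal(colnames(losses_a), colnames(losses_b))) {
    stop("model sets differ between the two loss matrices", call. = FALSE)
  }
  out <- rbind(losses_a, losses_b[, colnames(losses_a), drop = FALSE])
  attr(out, "horizon") <- paste(attr(losses_a, "horizon") %||% "a",
                                attr(losses_b, "horizon") %||% "b",
                                sep = "+")
  out
}

# ---- Plackett-Luce ranking ------------------------------------------------

#' Bayesian Plackett-Luce ranking of models
#'
#' Each observation row is converted to a ranking (lowest loss ranks first;
#' ties broken at random). The Plackett-Luce likelihood over the rankings is
#' combined with independent Gamma(`prior_concentration`, 1) priors on the
#' worth parameters -- equivalent, after normalization, to a Dirichlet prior
#' on the worth simplex -- and sampled by the exact conjugate Gibbs sampler
#' (latent exponential stage variables). Reported per model: the posterior
#' mean and 5--95% credible interval of its probability of ranking first.
#'
#' @param losses Observations x models loss matrix.
#' @param prior_concentration Dirichlet/Gamma shape parameter (1 = uniform).
#' @param n_samples Posterior draws kept (after `burn_in`).
#' @param burn_in Discarded initial Gibbs sweeps.
#' @param seed Integer seed.
#' @return A `pl_ranking` object with tibble `ranking` (model, p_best,
#'   lower, upper) and the posterior draws of the win probabilities.
#' @export
pl_ranking <- function(losses, prior_concentration = 1, n_samples = 2000,
                       burn_in = 200, seed = 1L) {
  losses <- check_losses(losses)
  n <- nrow(losses); m <- ncol(losses)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  tied <- apply(losses, 1, function(r) length(unique(r)) == 1)
  if (any(tied)) {
    warning(sum(tied), " all-tied observation row(s) dropped", call. = FALSE)
    losses <- losses[!tied, , drop = FALSE]
    n <- nrow(losses)
  }
  # orderings[i, ] = model indices from best to worst in observation i
  orderings <- t(apply(losses, 1, function(r) {
    order(rank(r, ties.method = "random"))
  }))
  # Gibbs: w_j | Z ~ Gamma(prior + wins_j, 1 + sum of Z over the stages in
  # which j was still in the running); Z_{i,s} | w ~ Exp(sum of remaining
  # worths at stage s of observation i)
  wins <- tabulate(orderings[, -m, drop = FALSE], nbins = m)
  w <- rep(1, m)
  draws <- matrix(0, n_samples, m)
  # stage membership: in observation i, stage s involves models ranked s..m
  for (it in seq_len(burn_in + n_samples)) {
    rates <- numeric(m)
    for (s in seq_len(m - 1)) {
      remaining <- orderings[, s:m, drop = FALSE]
      stage_sums <- matrix(w[remaining], nrow = n)
      z <- stats::rexp(n, rate = rowSums(stage_sums))
      zr <- rep(z, times = m - s + 1)
      contrib <- rowsum(zr, group = as.vector(remaining))
      rates[as.integer(rownames(contrib))] <-
        rates[as.integer(rownames(contrib))] + contrib[, 1]
    }
    w <- stats::rgamma(m, shape = prior_concentration + wins, rate = 1 + rates)
    if (it > burn_in) draws[it - burn_in, ] <- w / sum(w)
  }
  colnames(draws) <- colnames(losses)
  ranking <- tibble::tibble(
    model = colnames(losses),
    p_best = colMeans(draws),
    lower = apply(draws, 2, stats::quantile, 0.05),
    upper = apply(draws, 2, stats::quantile, 0.95)
  )
  ranking <- dplyr::arrange(ranking, dplyr::desc(.data$p_best))
  structure(list(ranking = ranking, draws = draws), class = "pl_ranking")
}

#' @export
print.pl_ranking <- function(x, ...) {
  cat("Plackett-Luce posterior probability of being the best model\n")
  print(x$ranking)
  invisible(x)
}

# ---- stationary bootstrap -------------------------------------------------

# Politis-Romano stationary bootstrap index matrix (n x B), expected block
# length `block_length`.
stationary_bootstrap_indices <- function(n, B, block_length = 5) {
  p <- 1 / block_length
  idx <- matrix(0L, n, B)
  idx[1, ] <- sample.int(n, B, replace = TRUE)
  if (n > 1) {
    for (t in 2:n) {
      restart <- stats::runif(B) < p
      nxt <- idx[t - 1, ] %% n + 1L
      nxt[restart] <- sample.int(n, sum(restart), replace = TRUE)
      idx[t, ] <- nxt
    }
  }
  idx
}

# bootstrap column means of x (n x m) for each replicate: returns m x B
bootstrap_means <- function(x, idx) {
  res <- apply(idx, 2, function(i) colMeans(x[i, , drop = FALSE]))
  if (is.null(dim(res))) res <- matrix(res, nrow = 1)
  res
}

# ---- Model Confidence Set -------------------------------------------------

#' Model Confidence Set by iterative bootstrap elimination
#'
#' Implements the T_max elimination procedure: at each step the studentized
#' maximum of the mean loss differentials (each model against the average of
#' the current set) is compared with its stationary-bootstrap null; while
#' the hypothesis of equal predictive ability is rejected the worst model is
#' eliminated. Eliminated models receive monotonized p-values; survivors at
#' level `alpha` form the confidence set, and the last survivor has p = 1.
#'
#' @param losses Observations x models loss matrix.
#' @param alpha Confidence level of the set.
#' @param n_bootstrap Bootstrap replications.
#' @param block_length Expected stationary-bootstrap block length.
#' @param seed Integer seed.
#' @return An `mcs_result`: tibble `p_values` (model, p, in_set), the
#'   survivor set and the elimination order.
#' @export
mcs <- function(losses, alpha = 0.05, n_bootstrap = 1000, block_length = 5,
                seed = 1L) {
  losses <- check_losses(losses)
  n <- nrow(losses)
  if (n < 10) stop("need at least 10 observations", call. = FALSE)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  idx <- stationary_bootstrap_indices(n, n_bootstrap, block_length)
  boot_means <- t(bootstrap_means(losses, idx)) # B x m
  full_means <- colMeans(losses)
  models <- colnames(losses)
  in_play <- models
  elim <- character(0)
  p_seq <- numeric(0)
  p_running <- 0
  while (length(in_play) > 1) {
    mcols <- match(in_play, models)
    k <- length(mcols)
    mu <- full_means[mcols]
    d_bar <- (mu - mean(mu)) * k / (k - 1)
    bm <- boot_means[, mcols, drop = FALSE]
    d_star <- (bm - rowMeans(bm)) * k / (k - 1)
    d_star <- sweep(d_star, 2, d_bar) # centered bootstrap differentials
    v <- colMeans(d_star^2)
    v[v < 1e-20] <- 1e-20
    t_stat <- d_bar / sqrt(v)
    t_max <- max(t_stat)
    t_star <- apply(sweep(d_star, 2, sqrt(v), `/`), 1, max)
    p_here <- mean(t_star >= t_max)
    p_running <- max(p_running, p_here) # monotonized MCS p-values
    worst <- in_play[which.max(t_stat)]
    elim <- c(elim, worst)
    p_seq <- c(p_seq, p_running)
    in_play <- setdiff(in_play, worst)
  }
  elim <- c(elim, in_play)
  p_seq <- c(p_seq, 1)
  p_values <- tibble::tibble(model = elim, p = p_seq,
                             in_set = p_seq > alpha)
  p_values <- p_values[match(models, p_values$model), ]
  structure(list(p_values = p_values,
                 survivors = p_values$model[p_values$in_set],
                 elimination_order = elim, alpha = alpha),
            class = "mcs_result")
}

#' @export
print.mcs_result <- function(x, ...) {
  cat("Model Confidence Set (alpha = ", x$alpha, ")\n", sep = "")
  print(x$p_values)
  invisible(x)
}

# ---- Superior Predictive Ability -----------------------------------------

#' Superior Predictive Ability test
#'
#' Tests whether any competitor has superior predictive ability over the
#' benchmark model. Relative performance is `d_k(t) = loss(benchmark, t) -
#' loss(k, t)` (positive mean: competitor k beats the benchmark); the
#' statistic is the studentized maximum of sqrt(n) mean(d_k), and the null
#' distribution comes from a stationary bootstrap under three re-centerings
#' of the competitor means -- lower (significantly bad competitors keep
#' their deficit), consistent (the recommended data-dependent threshold) and
#' upper (all competitors re-centered to equality) -- giving ordered
#' p-values lower <= consistent <= upper. A high consistent p-value means no
#' competitor beats the benchmark.
#'
#' @param losses Observations x models loss matrix.
#' @param benchmark Column name of the benchmark model.
#' @param n_bootstrap Bootstrap replications.
#' @param block_length Expected stationary-bootstrap block length.
#' @param seed Integer seed.
#' @return An `spa_result` tibble row: benchmark, p_lower, p_consistent,
#'   p_upper.
#' @export
spa <- function(losses, benchmark, n_bootstrap = 1000, block_length = 5,
                seed = 1L) {
  losses <- check_losses(losses)
  if (!benchmark %in% colnames(losses)) {
    stop("benchmark '", benchmark, "' not in the model set", call. = FALSE)
  }
  if (ncol(losses) < 2) stop("no competitor models", call. = FALSE)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  n <- nrow(losses)
  d <- losses[, benchmark] - losses[, setdiff(colnames(losses), benchmark),
                                    drop = FALSE]
  d_bar <- colMeans(d)
  idx <- stationary_bootstrap_indices(n, n_bootstrap, block_length)
  d_star <- t(bootstrap_means(d, idx)) # B x k
  omega2 <- n * colMeans(sweep(d_star, 2, d_bar)^2)
  omega2[omega2 < 1e-20] <- 1e-20
  omega <- sqrt(omega2)
  t_obs <- max(0, max(sqrt(n) * d_bar / omega))
  a_k <- sqrt(omega2 / n * 2 * log(log(max(n, 3))))
  centers <- list(
    lower = pmin(d_bar, 0),
    consistent = d_bar * (d_bar <= -a_k),
    upper = rep(0, length(d_bar))
  )
  p <- vapply(centers, function(mu) {
    z <- sweep(d_star, 2, d_bar - mu) # recentered bootstrap means
    t_star <- apply(sweep(z, 2, omega / sqrt(n), `/`), 1, function(r) max(0, max(r)))
    mean(t_star >= t_obs)
  }, numeric(1))
  out <- tibble::tibble(benchmark = benchmark, p_lower = p[["lower"]],
                        p_consistent = p[["consistent"]],
                        p_upper = p[["upper"]])
  class(out) <- c("spa_result", class(out))
  out
}
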