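rand_losses <- function(n, m, seed, shift = NULL) {
  set.seed(seed)
  L <- matrix(rexp(n * m, rate = 1 / 20), n, m)
  if (!is.null(shift)) L <- sweep(L, 2, shift, `+`)
  colnames(L) <- paste0("m", seq_len(m))
  L
}

test_that("a model that wins every observation dominates the PL ranking", {
  set.seed(1)
  L <- rand_losses(50, 3, seed = 2)
  L[, 2] <- L[, 1] + rexp(50, 1 / 10) + 0.5 # m1 first in every row
  L[, 3] <- L[, 1] + rexp(50, 1 / 10) + 0.5
  stopifnot(all(apply(L, 1, which.min) == 1))
  r <- pl_ranking(L, seed = 5)
  expect_equal(r$ranking$model[1], "m1")
  expect_gt(r$ranking$p_best[1], 0.9)
  # win probabilities live on the simplex, draw by draw
  expect_equal(rowSums(r$draws), rep(1, nrow(r$draws)), tolerance = 1e-12)
  expect_equal(sum(r$ranking$p_best), 1, tolerance = 1e-12)
})

test_that("exchangeable losses give near-uniform win probabilities", {
  L <- rand_losses(200, 4, seed = 7)
  r <- pl_ranking(L, seed = 8)
  expect_true(all(abs(r$ranking$p_best - 0.25) < 0.08))
})

test_that("PL ranking handles ties, duplicates and rescaling", {
  L <- rand_losses(60, 3, seed = 9)
  # a duplicated model shares the win probability of its twin
  L2 <- cbind(L, m3bis = L[, 3])
  r2 <- pl_ranking(L2, seed = 10)
  p <- r2$ranking
  expect_lt(abs(p$p_best[p$model == "m3"] - p$p_best[p$model == "m3bis"]),
            0.05)
  # rankings are scale-free
  r_a <- pl_ranking(L, seed = 11)
  r_b <- pl_ranking(L * 7, seed = 11)
  expect_equal(r_a$ranking, r_b$ranking)
  # all-tied rows are dropped with a warning
  L3 <- rbind(L, matrix(5, 2, 3, dimnames = list(NULL, colnames(L))))
  expect_warning(pl_ranking(L3, seed = 12), "tied")
  # reproducible under a fixed seed
  expect_identical(pl_ranking(L, seed = 13)$draws,
                   pl_ranking(L, seed = 13)$draws)
})

test_that("MCS always eliminates a strictly dominated model and keeps one survivor", {
  L <- rand_losses(40, 2, seed = 20)
  L[, 2] <- L[, 1] + 10
  r <- mcs(L, seed = 21)
  expect_equal(r$survivors, "m1")
  expect_equal(r$p_values$p[r$p_values$model == "m1"], 1)
  expect_lt(r$p_values$p[r$p_values$model == "m2"], 0.05)

  # ties: identical models are both retained
  Lt <- cbind(m1 = rand_losses(40, 1, seed = 22)[, 1])
  Lt <- cbind(Lt, m2 = Lt[, 1])
  rt <- mcs(Lt, seed = 23)
  expect_setequal(rt$survivors, c("m1", "m2"))

  # the survivor set is never empty and p-values are monotone in elimination
  L5 <- rand_losses(60, 5, seed = 24, shift = c(0, 2, 4, 8, 16))
  r5 <- mcs(L5, seed = 25)
  expect_gte(length(r5$survivors), 1)
  p_elim <- r5$p_values$p[match(r5$elimination_order, r5$p_values$model)]
  expect_true(all(diff(p_elim) >= 0))
})

test_that("SPA p-values capture dominance in both directions and stay ordered", {
  # benchmark strictly better than every competitor
  L <- rand_losses(40, 3, seed = 30)
  L[, 2] <- L[, 1] + 10; L[, 3] <- L[, 1] + 10
  r <- spa(L, "m1", seed = 31)
  expect_gte(r$p_consistent, 0.95)
  # benchmark strictly dominated
  r2 <- spa(L, "m2", seed = 32)
  expect_lte(r2$p_consistent, 0.05)
  # ordering lower <= consistent <= upper across random matrices
  for (s in 1:40) {
    Lr <- rand_losses(25, 4, seed = 100 + s,
                      shift = runif(4, 0, 5))
    rr <- spa(Lr, "m2", n_bootstrap = 200, seed = s)
    expect_lte(rr$p_lower, rr$p_consistent + 1e-12)
    expect_lte(rr$p_consistent, rr$p_upper + 1e-12)
  }
})

test_that("multi-horizon concatenation stacks aligned loss matrices", {
  a <- rand_losses(60, 3, seed = 40)
  b <- rand_losses(60, 3, seed = 41)
  ab <- multi_horizon(a, b)
  expect_equal(nrow(ab), 120)
  expect_equal(colMeans(ab), (colMeans(a) + colMeans(b)) / 2)
  # column order of the second matrix does not matter
  ab2 <- multi_horizon(a, b[, c(2, 3, 1)])
  expect_equal(ab, ab2, ignore_attr = TRUE)
  expect_error(multi_horizon(a, b[, 1:2]), "model sets differ")
  # comparison outcomes are stable under concatenation order up to
  # bootstrap noise: survivors under clear separation are identical
  sep_a <- rand_losses(50, 3, seed = 42, shift = c(0, 0, 25))
  sep_b <- rand_losses(50, 3, seed = 43, shift = c(0, 0, 25))
  m1 <- mcs(multi_horizon(sep_a, sep_b), seed = 44)
  m2 <- mcs(multi_horizon(sep_b, sep_a), seed = 44)
  expect_setequal(m1$survivors, m2$survivors)
})

test_that("all three procedures are invariant to a common rescaling of losses", {
  L <- rand_losses(40, 3, seed = 50, shift = c(0, 1, 6))
  m_a <- mcs(L, seed = 51)
  m_b <- mcs(L * 7, seed = 51)
  expect_equal(m_a$p_values, m_b$p_values)
  s_a <- spa(L, "m1", seed = 52)
  s_b <- spa(L * 7, "m1", seed = 52)
  expect_equal(s_a, s_b)
  expect_equal(pl_ranking(L, seed = 53)$ranking,
               pl_ranking(L * 7, seed = 53)$ranking)
})

test_that("loss matrices assemble from tidy losses and reject missing cells", {
  tidy <- tidyr::expand_grid(patient_id = c("a", "b"), fold = 1:3,
                             model = c("x", "y"))
  tidy$loss <- seq_len(nrow(tidy))
  tidy$horizon <- 30
  L <- loss_matrix(tidy)
  expect_equal(dim(L), c(6, 2))
  expect_equal(colnames(L), c("x", "y"))
  expect_error(loss_matrix(tidy[-1, ]), "missing")
})
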