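test_that("built models reproduce the published parameter counts exactly", {
  audit <- audit_parameters()
  printed <- c(mirshekarian = 206, meijner = 154, gulesir = 181, sun = 1053,
               idriss = 13491, aiello = 101249, zhu = 5377, mayo = 22366)
  for (sp in names(printed)) {
    expect_equal(audit$built[audit$spec_id == sp], unname(printed[[sp]]),
                 info = sp)
  }
})

test_that("every catalog entry builds and maps a window batch to finite output", {
  X <- array(runif(4 * 25 * 4), dim = c(4, 25, 4))
  for (sp in setdiff(zoo_spec_ids(), c("khadem", "ensemble_mms",
                                       "ensemble_mmsz"))) {
    m <- build_model(sp, seed = 2)
    out <- glybench:::predict_raw(m, X)
    expect_true(all(is.finite(out)), info = sp)
    expect_equal(nrow(out), 4, info = sp)
  }
  # composite and ensembles build too
  expect_s3_class(build_model("khadem"), "glybench_composite")
  expect_s3_class(build_model("ensemble_mms"), "glybench_ensemble")
  expect_named(build_model("ensemble_mmsz")$members,
               c("mirshekarian", "meijner", "sun", "zhu"))
})

test_that("unknown specs and incompatible wiring are rejected", {
  expect_error(build_model("nonexistent"), "unknown spec_id")
  # the two-branch model needs all four channels over 25 steps
  expect_error(build_model("aiello", input_steps = 10, n_features = 2),
               "incompatible")
})

test_that("the Gaussian likelihood head matches its closed form", {
  # at the mode with unit variance the per-sample loss is log(2*pi)/2
  expect_equal(gaussian_nll(1.5, 1.5, 1), 0.5 * log(2 * pi))
  # one standard deviation away adds exactly 1/2
  expect_equal(gaussian_nll(2.5, 1.5, 1), 0.5 * log(2 * pi) + 0.5)
  # doubling sigma at the mode adds log 2
  expect_equal(gaussian_nll(1.5, 1.5, 2) - gaussian_nll(1.5, 1.5, 1), log(2))
  expect_error(gaussian_nll(1, 1, 0), "positive")
  # the training head agrees with the reference form (ELU+1 link)
  out <- cbind(c(1.2, 0.9), c(0.3, -0.2))
  sigma <- ifelse(out[, 2] > 0, out[, 2], exp(out[, 2]) - 1) + 1 + 1e-6
  lb <- glybench:::loss_forward_backward("gaussian_nll", out, c(1.0, 1.1))
  expect_equal(lb$loss, gaussian_nll(c(1.0, 1.1), out[, 1], sigma))
})

test_that("risk encoding is a monotone, invertible-within-a-bin transform", {
  bg <- 40:400
  bins <- risk_encode(bg)
  expect_true(all(diff(bins) >= 0))
  expect_true(all(bins >= 0 & bins <= 99))
  expect_lt(risk_encode(70), risk_encode(180))
  # round-trip error bounded by one bin width on the glucose scale
  back <- risk_decode(bins)
  width <- risk_decode(pmin(99, bins + 1)) - risk_decode(pmax(0, bins - 1))
  expect_true(all(abs(back - bg) <= width))
  # the transform spans [-2, 2] between the sensor bounds
  expect_equal(glybench:::risk_transform(40), -2)
  expect_equal(glybench:::risk_transform(400), 2)
  expect_error(risk_encode(30), "outside")
  expect_error(risk_decode(120), "outside")
})

test_that("ensemble prediction is the clipped arithmetic member mean", {
  expect_equal(ensemble_predict(list(100, 110, 120)), 110)
  # idempotent on identical members
  p <- c(90, 180, 260)
  expect_equal(ensemble_predict(list(p, p, p)), p)
  # clipping after averaging
  expect_equal(ensemble_predict(list(500, 500, 500)), 400)
  # permutation invariant and bounded by the member envelope
  a <- runif(20, 80, 120); b <- runif(20, 100, 200); c <- runif(20, 60, 300)
  e1 <- ensemble_predict(list(a, b, c))
  e2 <- ensemble_predict(list(c, a, b))
  expect_equal(e1, e2)
  expect_true(all(e1 >= pmin(a, b, c) & e1 <= pmax(a, b, c)))
  expect_error(ensemble_predict(list(a)), "two member")
  expect_error(ensemble_predict(list(a, b[1:3])), "aligned")
})

test_that("the PLSR learner recovers a linear map and feeds the stack", {
  set.seed(8)
  X <- matrix(rnorm(300), 100, 3)
  y <- X %*% c(2, -1, 0.5) + 0.3
  fit <- glybench:::plsr_fit(X, drop(y), ncomp = 3)
  expect_lt(max(abs(glybench:::plsr_predict(fit, X) - drop(y))), 1e-8)
  # rank-deficient input degrades gracefully
  X2 <- cbind(X[, 1], X[, 1], X[, 2])
  fit2 <- glybench:::plsr_fit(X2, drop(y), ncomp = 3)
  expect_true(all(is.finite(glybench:::plsr_predict(fit2, X2))))
})
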