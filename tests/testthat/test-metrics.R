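test_that("perfect and mean predictors hit the closed-form limits", {
  a <- c(90, 120, 180, 240, 150)
  perfect <- compute_metrics(tibble::tibble(actual = a, predicted = a))
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$cc, 1)
  expect_equal(perfect$fit, 1)
  expect_equal(perfect$mard, 0)

  null <- compute_metrics(tibble::tibble(actual = a,
                                         predicted = rep(mean(a), 5)))
  expect_equal(null$r2, 0)
  expect_equal(null$fit, 0)
})

test_that("a hand-checkable pair gives the arithmetic of the definitions", {
  m <- compute_metrics(tibble::tibble(actual = c(100, 200),
                                      predicted = c(110, 180)))
  expect_equal(m$mae, 15)
  expect_equal(m$mse, (100 + 400) / 2)
  expect_equal(m$rmse, sqrt(250))
  expect_equal(m$mard, (10 / 100 + 20 / 200) / 2)
})

test_that("the suite agrees with naive-loop oracles on random prediction sets", {
  set.seed(19)
  worst <- 0
  for (i in 1:300) {
    n <- sample(5:60, 1)
    a <- runif(n, 41, 399)
    p <- pmin(400, pmax(40, a + rnorm(n, 0, 25)))
    got <- compute_metrics(tibble::tibble(actual = a, predicted = p))
    want <- oracle_metrics(a, p)
    for (k in names(want)) {
      worst <- max(worst, abs(got[[k]] - want[[k]]))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("metric invariances hold", {
  set.seed(23)
  a <- runif(50, 60, 320)
  p <- a + rnorm(50, 0, 20)
  base <- compute_metrics(tibble::tibble(actual = a, predicted = p))
  # Pearson correlation is invariant to positive affine maps of predictions
  aff <- compute_metrics(tibble::tibble(actual = a, predicted = 3 * p + 7))
  expect_equal(aff$cc, base$cc)
  # MARD is scale-free
  sc <- compute_metrics(tibble::tibble(actual = 2 * a, predicted = 2 * p))
  expect_equal(sc$mard, base$mard)
  expect_equal(sc$rmse, 2 * base$rmse)
})

test_that("degenerate inputs disable only the variance-normalized metrics", {
  expect_warning(
    out <- compute_metrics(tibble::tibble(actual = c(100, 100),
                                          predicted = c(90, 110))),
    "undefined")
  expect_true(is.na(out$r2) && is.na(out$cc) && is.na(out$fit))
  expect_equal(out$mae, 10)
  expect_error(compute_metrics(tibble::tibble(actual = c(-1, 100),
                                              predicted = c(1, 1))),
               "positive")
})

test_that("patient aggregation returns mean and standard error of the mean", {
  rows <- tibble::tibble(patient_id = c("a", "b"), model = "m", horizon = 30,
                         rmse = c(18, 22))
  agg <- aggregate_patients(rows)
  expect_equal(agg$mean[agg$metric == "rmse"], 20)
  # sd = 2*sqrt(2), sem = sd/sqrt(2) = 2
  expect_equal(agg$sem[agg$metric == "rmse"], 2)
  # identical rows: zero dispersion
  same <- tibble::tibble(patient_id = c("a", "b"), model = "m", horizon = 30,
                         rmse = c(20, 20))
  expect_equal(aggregate_patients(same)$sem, 0)
  # permutation invariance in the patients
  perm <- aggregate_patients(rows[2:1, ])
  expect_equal(perm, agg)
  # single patient: SEM absent
  one <- aggregate_patients(rows[1, ])
  expect_true(is.na(one$sem))
  # folds are averaged within patient before crossing patients
  folds <- tibble::tibble(patient_id = c("a", "a", "b", "b"),
                          model = "m", horizon = 30,
                          rmse = c(17, 19, 21, 23))
  expect_equal(aggregate_patients(folds)$mean, 20)
  expect_equal(aggregate_patients(folds)$sem, 2)
})

test_that("the wide report table renders models by metrics with mean and SEM", {
  rows <- tibble::tibble(patient_id = rep(c("a", "b"), 2),
                         model = rep(c("m1", "m2"), each = 2), horizon = 30,
                         rmse = c(18, 22, 30, 34), mard = c(0.1, 0.1, 0.2, 0.2))
  wide <- format_metric_table(aggregate_patients(rows))
  expect_equal(names(wide), c("model", "horizon", "rmse", "mard"))
  expect_equal(wide$rmse[wide$model == "m1"], "20.00 ± 2.00")
  expect_equal(wide$mard[wide$model == "m2"], "0.20 ± 0.00")
})
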