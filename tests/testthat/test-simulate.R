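test_that("glucose sits at its fixed point without meals or insulin", {
  cfg <- sim_config(n_patients = 1, days = 1, meals_per_day = 0,
                    basal_rate = 0, noise_sd = 0, gap_rate = 0, seed = 3)
  s <- simulate_patient(cfg, 1)
  expect_equal(s$bg, rep(cfg$gb, nrow(s)))
})

test_that("a single meal produces a rise-then-relax excursion peaking at 30-90 min", {
  cfg <- sim_config(n_patients = 1, days = 1, meals_per_day = 0,
                    basal_rate = 0, noise_sd = 0, gap_rate = 0, seed = 3)
  s <- simulate_patient(cfg, 1)
  meal_step <- 60
  s$ch[meal_step] <- 60 # 60 g, no bolus: pure carbohydrate response
  bg <- glybench:::simulate_glucose(cfg, s$ch, bol = numeric(nrow(s)),
                                    bas = numeric(nrow(s)), n = nrow(s), dt = 5)
  peak <- which.max(bg)
  peak_min <- (peak - meal_step) * 5
  expect_gt(bg[peak], cfg$gb + 30) # a real excursion
  expect_gte(peak_min, 30)
  expect_lte(peak_min, 90)
  # strictly rising to the peak (absorption starts one step after the
  # meal), relaxing toward baseline afterwards
  expect_true(all(diff(bg[(meal_step + 1):peak]) > 0))
  expect_lt(bg[nrow(s)], bg[peak])
  # seeded regression value for the peak of the default-parameter response
  expect_equal(bg[peak], 266.661075, tolerance = 1e-8)
})

test_that("simulation is deterministic in the seed", {
  cfg <- sim_config(n_patients = 2, days = 2, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c2 <- simulate_cohort(sim_config(n_patients = 2, days = 2, seed = 12))
  expect_false(identical(a$bg, c2$bg))
})

test_that("simulated cohorts satisfy every series invariant", {
  cfg <- sim_config(n_patients = 3, days = 4, seed = 21)
  s <- simulate_cohort(cfg, gaps = FALSE)
  expect_silent(validate_cgm_series(s))
  expect_equal(nrow(s), 3 * 4 * 288)
  # last 20% of each record is the test partition
  frac <- tapply(s$split == "test", s$patient_id, mean)
  expect_true(all(abs(frac - 0.2) < 0.01))
})

test_that("gap injection masks the requested spans and protects endpoints", {
  cfg <- sim_config(n_patients = 1, days = 2, gap_rate = 0, seed = 5)
  s <- simulate_patient(cfg, 1)
  expect_identical(inject_gaps(s, cfg), s)

  # one 30-minute gap means exactly 6 missing samples
  cfg1 <- sim_config(n_patients = 1, days = 2, gap_rate = 100, seed = 5,
                     gap_length = c(30, 30))
  one_gap_cfg <- sim_config(n_patients = 1, days = 2, gap_rate = 0.5,
                            gap_length = c(30, 30), seed = 37)
  g <- inject_gaps(s, one_gap_cfg)
  expect_equal(sum(is.na(g$bg)), 6)
  runs <- rle(is.na(g$bg))
  expect_equal(sum(runs$values), 1)

  # determinism
  g2 <- inject_gaps(s, one_gap_cfg)
  expect_identical(g, g2)

  # endpoints of both partitions survive and over-masking errors out
  expect_error(inject_gaps(s, cfg1), "50%")
  g3 <- inject_gaps(s, sim_config(n_patients = 1, days = 2, gap_rate = 3,
                                  seed = 6))
  for (part in c("train", "test")) {
    rows <- which(g3$split == part)
    expect_false(is.na(g3$bg[rows[1]]))
    expect_false(is.na(g3$bg[rows[length(rows)]]))
  }
})

test_that("spline filling recovers the smooth simulated trace inside short gaps", {
  cfg <- sim_config(n_patients = 1, days = 3, noise_sd = 0, gap_rate = 2,
                    gap_length = c(10, 30), seed = 9)
  truth <- simulate_patient(cfg, 1)
  gappy <- inject_gaps(truth, cfg)
  expect_gt(sum(is.na(gappy$bg)), 0)
  filled <- fill_gaps(gappy)
  expect_lt(max(abs(filled$bg - truth$bg)), 5)
})
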