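test_that("series constructor enforces the grid and channel invariants", {
  s <- toy_series(50)
  expect_s3_class(s, "cgm_series")
  expect_equal(diff(s$time), rep(5, 49))

  expect_error(cgm_series("p", bg = c(120, 30, 120)), "CGM range")
  expect_error(cgm_series("p", bg = c(120, 121), bol = c(-1, 0)),
               "non-negative")
  bad <- toy_series(20, split_at = 10)
  bad$split[3] <- "test" # test row before train rows
  expect_error(validate_cgm_series(bad), "suffix")
})

test_that("the csv dialect round-trips a cohort with gaps and split", {
  s <- dplyr::bind_rows(toy_series(60, pid = "a", split_at = 40),
                        toy_series(80, pid = "b"))
  s <- as_cgm_series(s)
  s$bg[c(10, 11, 12, 70)] <- NA
  dir <- withr::local_tempdir()
  write_cgm_csv(s, dir)
  back <- read_cgm_csv(dir)
  expect_equal(back$bg, s$bg)
  expect_equal(back$split, s$split)
  expect_equal(back$ch, s$ch)
})

test_that("gap filling interpolates, clips, and refuses bad inputs", {
  # no gaps: identity
  s <- toy_series(40)
  expect_equal(fill_gaps(s)$bg, s$bg)

  # constant series: the gap is filled with the constant
  s2 <- cgm_series("p", bg = rep(120, 9))
  s2$bg[5] <- NA
  expect_equal(fill_gaps(s2)$bg[5], 120)

  # cubic data: an interior gap is reproduced exactly (value checked
  # against an independent cubic-spline routine: 4^3 = 64)
  tt <- c(0, 1, 2, 3, 5, 6, 7, 8)
  s3 <- cgm_series("p", bg = rep(100, 9))
  s3$bg <- c(40 + tt^3 / 10, NA)[order(c(tt, 4))]
  expect_equal(fill_gaps(s3)$bg[5], 40 + 64 / 10, tolerance = 1e-10)

  # fewer than 4 anchors
  s4 <- cgm_series("p", bg = rep(100, 8))
  s4$bg[3:8] <- NA
  expect_error(fill_gaps(s4), "unfillable")

  # trailing gap: no extrapolation
  s5 <- cgm_series("p", bg = rep(100, 8))
  s5$bg[8] <- NA
  expect_error(fill_gaps(s5), "extrapolate")

  # interpolated values are clipped into the hardware range
  s6 <- cgm_series("p", bg = c(40, 41, 43, 40, NA, 40, 44, 41, 40))
  expect_gte(min(fill_gaps(s6)$bg), 40)
})

test_that("gap filling is idempotent and flags long gaps", {
  s <- toy_series(100)
  s$bg[30:45] <- NA # 80-minute gap
  expect_warning(f1 <- fill_gaps(s), "longer than 60 min")
  expect_warning(f2 <- fill_gaps(f1), NA)
  expect_equal(f2$bg, f1$bg)
  expect_true(all(f1$bg_imputed[30:45]))
})

test_that("feature scaling is train-fitted, bounded and invertible", {
  s <- toy_series(100, split_at = 80)
  s$ch <- c(rep(0, 50), rep(80, 30), rep(200, 20)) # test max exceeds train max
  sc <- scale_features(s)
  expect_equal(sc$bg, s$bg * 0.01)
  # midpoint of the training range maps to 0.5
  stats <- attr(sc, "scale_stats")
  expect_equal(stats$max[stats$channel == "ch"], 80)
  sc2 <- scale_features(dplyr::mutate(s, ch = 40), stats = stats)
  expect_equal(unique(sc2$ch), 0.5)
  # constant channel maps to zero without division error
  s$bol <- 0
  expect_equal(unique(scale_features(s)$bol), 0)
  # invalid stats
  bad <- tibble::tibble(channel = c("bg", "bas", "bol", "ch"),
                        min = 1, max = 0)
  expect_error(scale_features(s, stats = bad), "invalid")
  # round trip of the glucose channel is exact
  expect_equal(unscale_bg(sc$bg), s$bg)
})

test_that("window counts follow the closed form and respect the partition", {
  # minimal length: L = 31 with a 30-min horizon gives exactly 1 window
  s <- scale_features(toy_series(31))
  expect_equal(dim(make_windows(s, horizons = 30)$inputs)[1], 1)

  s100 <- scale_features(toy_series(100))
  expect_equal(dim(make_windows(s100, horizons = 30)$inputs)[1], 70)
  w3 <- make_windows(s100, horizons = c(30, 60, 120))
  expect_equal(dim(w3$inputs)[1], 52)
  expect_length(w3$targets, 3)

  # property: count = L - 24 - max_h for every feasible L (enumeration)
  for (L in c(25, 31, 49, 77, 128, 200)) {
    ds <- suppressWarnings(
      make_windows(scale_features(toy_series(L)), horizons = 30))
    expect_equal(dim(ds$inputs)[1], max(0, L - 24 - 6))
  }

  # too short: empty dataset with a warning, not an error
  expect_warning(ds0 <- make_windows(scale_features(toy_series(30)),
                                     horizons = 30), "too short")
  expect_equal(dim(ds0$inputs)[1], 0)

  # windows never straddle the train/test boundary
  sp <- scale_features(toy_series(120, split_at = 60))
  dsp <- make_windows(sp, horizons = 30)
  expect_equal(as.integer(table(dsp$meta$partition)[c("train", "test")]),
               c(30, 30))
  # each target really is the glucose ph minutes after the window end
  i <- 5
  end_time <- dsp$meta$time[i]
  expect_equal(dsp$targets[["30"]][i], sp$bg[sp$time == end_time + 30])
})

test_that("prediction clipping bounds to the sensor range and rejects NaN", {
  expect_equal(clip_predictions(c(120, 10, 1000)), c(120, 40, 400))
  expect_error(clip_predictions(c(120, NaN), model_id = "sun"), "sun")
})
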