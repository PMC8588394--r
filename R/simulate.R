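#' Configuration for the synthetic CGM cohort generator
#'
#' The generator emulates the shape of an eight-week type-1-diabetes CGM
#' study: per-patient 5-minute series of glucose, basal insulin rate, meal
#' boluses and carbohydrate intakes, with sensor noise and missing-sample
#' gaps, and the final 20% of each record held out as the test partition.
#'
#' Glucose follows a minimal one-compartment model integrated on the 5-minute
#' grid: first-order return to a basal level `gb` at rate `k1`, a rise driven
#' by a two-stage (linear-rise, exponential-decay) carbohydrate absorption
#' kernel with time constant `tau_carb` and gain `k2`, and a fall driven by
#' the analogous insulin-action kernel (`tau_ins`, gain `k3`) fed by the
#' boluses and by deviations of the basal rate from its prescription (the
#' prescribed basal is the patient's steady state, folded into `gb`). Meals
#' arrive as a per-day Poisson process; each meal is paired with a bolus of
#' `carbs / carb_ratio` units.
#'
#' @param n_patients Number of patients.
#' @param days Days of recording per patient.
#' @param meals_per_day Expected meals per day (Poisson rate).
#' @param carb_range Meal size range in grams (uniform).
#' @param carb_ratio Carbohydrate-to-insulin ratio, g per unit.
#' @param basal_rate Basal insulin rate, U/h.
#' @param gb Basal glucose level, mg/dL.
#' @param k1 Glucose effectiveness (return-to-baseline rate), 1/min.
#' @param k2 Glycemic gain of carbohydrate, mg/dL per g.
#' @param k3 Glycemic drop per insulin unit, mg/dL per U.
#' @param tau_carb,tau_ins Absorption time constants, minutes.
#' @param noise_sd Sensor noise standard deviation, mg/dL.
#' @param gap_rate Expected sensor gaps per day.
#' @param gap_length Gap length range in minutes.
#' @param test_fraction Fraction of each record labelled test (suffix).
#' @param seed Integer seed; fully determines the cohort.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 6, days = 56, meals_per_day = 3.5,
                       carb_range = c(20, 100), carb_ratio = 10,
                       basal_rate = 1.0, gb = 130, k1 = 0.008, k2 = 3.5,
                       k3 = 30, tau_carb = 20, tau_ins = 55, noise_sd = 5,
                       gap_rate = 1, gap_length = c(15, 60),
                       test_fraction = 0.2, seed = 1L) {
  cfg <- list(n_patients = n_patients, days = days,
              meals_per_day = meals_per_day, carb_range = carb_range,
              carb_ratio = carb_ratio, basal_rate = basal_rate, gb = gb,
              k1 = k1, k2 = k2, k3 = k3, tau_carb = tau_carb,
              tau_ins = tau_ins, noise_sd = noise_sd, gap_rate = gap_rate,
              gap_length = gap_length, test_fraction = test_fraction,
              seed = as.integer(seed))
  stopifnot(n_patients >= 1, days >= 1, meals_per_day >= 0,
            carb_ratio > 0, gb > 40, k1 > 0, k2 >= 0, k3 >= 0,
            tau_carb > 0, tau_ins > 0, noise_sd >= 0, gap_rate >= 0,
            test_fraction >= 0, test_fraction < 1)
  structure(cfg, class = "sim_config")
}

# two-stage absorption kernel: x(t) = (t/tau^2) exp(-t/tau), unit integral
absorption_kernel <- function(tau, dt, len_min = 10 * tau) {
  t <- seq(0, len_min, by = dt)
  k <- (t / tau^2) * exp(-t / tau)
  k / sum(k * dt) # normalize so the discrete integral is 1
}

# convolve an event vector (amount at each step) with a kernel, same length
event_response <- function(events, kernel) {
  n <- length(events)
  out <- numeric(n)
  idx <- which(events > 0)
  for (i in idx) {
    span <- i:min(n, i + length(kernel) - 1)
    out[span] <- out[span] + events[i] * kernel[seq_along(span)]
  }
  out
}

#' Simulate one synthetic CGM patient
#'
#' @param config A [sim_config()].
#' @param patient_index 1-based patient index; combined with `config$seed` it
#'   determines the patient's random stream.
#' @return A gap-free `cgm_series` for one patient (gaps are injected
#'   separately by [inject_gaps()]).
#' @export
simulate_patient <- function(config, patient_index = 1) {
  stopifnot(inherits(config, "sim_config"))
  dt <- 5
  n <- config$days * 288L
  rng <- local_rng(config$seed + 7919L * patient_index)
  on.exit(rng(), add = TRUE)

  # meals: per-day Poisson counts, uniform times, uniform carb sizes
  ch <- numeric(n)
  for (d in seq_len(config$days)) {
    k <- stats::rpois(1, config$meals_per_day)
    if (k == 0) next
    steps <- (d - 1) * 288L + sample.int(288L, k)
    ch[steps] <- ch[steps] +
      round(stats::runif(k, config$carb_range[1], config$carb_range[2]))
  }
  bol <- ch / config$carb_ratio
  bas <- rep(config$basal_rate, n)

  bg <- simulate_glucose(config, ch, bol, bas, n, dt)

  n_test <- floor(config$test_fraction * n)
  split <- c(rep("train", n - n_test), rep("test", n_test))
  cgm_series(patient_id = sprintf("sim-%03d", patient_index),
             bg = bg, bas = bas, bol = bol, ch = ch, split = split)
}

simulate_glucose <- function(config, ch, bol, bas, n, dt) {
  ra <- config$k2 * event_response(ch, absorption_kernel(config$tau_carb, dt))
  ia <- config$k3 * event_response(bol, absorption_kernel(config$tau_ins, dt))
  # the prescribed basal rate is the patient's steady state (its effect is
  # folded into gb); only deviations from it act on glucose
  ia <- ia + config$k3 * (bas - config$basal_rate) / 60
  eps <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else numeric(n)
  bg <- numeric(n)
  bg[1] <- min(400, max(40, config$gb))
  for (t in seq_len(n - 1)) {
    drift <- config$k1 * (config$gb - bg[t]) * dt + (ra[t] - ia[t]) * dt
    bg[t + 1] <- min(400, max(40, bg[t] + drift + eps[t]))
  }
  bg
}

#' Remove glucose samples in contiguous blocks
#'
#' Emulates CGM sensor dropouts: per day, a Poisson number of gaps with
#' uniform lengths in `config$gap_length` minutes are placed at random
#' positions. The first and last sample of each train/test partition are
#' never removed, so the gap-filling step never has to extrapolate.
#'
#' @param x A gap-free `cgm_series`.
#' @param config A [sim_config()] (fields `gap_rate`, `gap_length`, `seed`).
#' @return The series with `NA` glucose values inside the injected gaps.
#' @export
inject_gaps <- function(x, config) {
  stopifnot(inherits(config, "sim_config"))
  if (anyNA(x$bg)) stop("series already has gaps", call. = FALSE)
  if (config$gap_rate == 0) return(x)
  out <- tibble::as_tibble(x)
  rng <- local_rng(config$seed + 104729L)
  on.exit(rng(), add = TRUE)
  for (pid in unique(out$patient_id)) {
    rows <- which(out$patient_id == pid)
    n <- length(rows)
    days <- n / 288
    n_gaps <- stats::rpois(1, config$gap_rate * days)
    if (n_gaps == 0) next
    protected <- logical(n)
    for (part in c("train", "test")) {
      in_part <- which(out$split[rows] == part)
      if (length(in_part) > 0) protected[range(in_part)] <- TRUE
    }
    drop <- logical(n)
    for (g in seq_len(n_gaps)) {
      len <- round(stats::runif(1, config$gap_length[1], config$gap_length[2]) / 5)
      start <- sample.int(n - len + 1, 1)
      drop[start:(start + len - 1)] <- TRUE
    }
    drop <- drop & !protected
    if (mean(drop) > 0.5) {
      stop("gap specification would mask more than 50% of patient ", pid,
           call. = FALSE)
    }
    out$bg[rows[drop]] <- NA_real_
  }
  new_cgm_series(out, sample_minutes = attr(x, "sample_minutes") %||% 5)
}

#' Simulate a cohort of synthetic patients
#'
#' @param config A [sim_config()].
#' @param gaps Inject sensor gaps after simulation.
#' @return A `cgm_series` with `config$n_patients` patients.
#' @export
simulate_cohort <- function(config, gaps = TRUE) {
  cohort <- dplyr::bind_rows(
    lapply(seq_len(config$n_patients), function(i) simulate_patient(config, i))
  )
  cohort <- new_cgm_series(cohort)
  if (gaps) cohort <- inject_gaps(cohort, config)
  cohort
}

# Seed the RNG from an integer, returning a restorer for the previous state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed %% .Machine$integer.max)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
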