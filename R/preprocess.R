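#' Fill sensor gaps with a cubic spline
#'
#' Missing glucose samples (NA runs) are interpolated by a cubic spline fitted
#' through the observed (time, bg) points, then clipped to the CGM hardware
#' range \[40, 400\] mg/dL. The spline uses the Forsythe--Malcolm--Moler end
#' condition (an exact cubic fitted through the four points nearest each end),
#' which reproduces cubic polynomials exactly on interior gaps. Only
#' interpolation is performed: a series whose first or last glucose value is
#' missing is rejected.
#'
#' Gaps longer than `flag_minutes` are filled all the same but flagged with a
#' warning, since long gaps carry the interpolation far from any observation.
#' The returned series gains a logical `bg_imputed` column.
#'
#' @param x A `cgm_series` (one or more patients).
#' @param flag_minutes Gap length above which a warning is emitted.
#' @return The gap-free `cgm_series` with a `bg_imputed` column.
#' @export
fill_gaps <- function(x, flag_minutes = 60) {
  dt <- attr(x, "sample_minutes") %||% 5
  out <- dplyr::group_modify(
    dplyr::group_by(tibble::as_tibble(x), .data$patient_id),
    function(p, key) fill_gaps_one(p, key$patient_id, dt, flag_minutes)
  )
  out <- dplyr::ungroup(out)
  new_cgm_series(out[c("patient_id", setdiff(names(out), "patient_id"))],
                 sample_minutes = dt)
}

fill_gaps_one <- function(p, pid, dt, flag_minutes) {
  obs <- !is.na(p$bg)
  p$bg_imputed <- !obs
  if (all(obs)) return(p)
  if (sum(obs) < 4) {
    stop("patient ", pid, ": fewer than 4 observed glucose values; ",
         "series is unfillable", call. = FALSE)
  }
  if (!obs[1] || !obs[length(obs)]) {
    stop("patient ", pid, ": leading or trailing gap; ",
         "spline interpolation cannot extrapolate", call. = FALSE)
  }
  sp <- stats::splinefun(p$time[obs], p$bg[obs], method = "fmm")
  p$bg[!obs] <- pmin(400, pmax(40, sp(p$time[!obs])))
  gap_runs <- rle(!obs)
  long <- gap_runs$values & gap_runs$lengths * dt > flag_minutes
  if (any(long)) {
    warning("patient ", pid, ": filled ", sum(long), " gap(s) longer than ",
            flag_minutes, " min", call. = FALSE)
  }
  p
}

#' Per-feature scaling statistics from the training partition
#'
#' @param x A `cgm_series`.
#' @return A tibble with one row per scaled channel (`bas`, `bol`, `ch`, and
#'   `bg` when `bg_minmax` scaling is requested later) holding the training
#'   minimum and maximum.
#' @export
compute_scale_stats <- function(x) {
  train <- tibble::as_tibble(x)[x$split == "train", ]
  purrr::map_dfr(c("bg", "bas", "bol", "ch"), function(chan) {
    v <- train[[chan]]
    tibble::tibble(channel = chan,
                   min = min(v, na.rm = TRUE),
                   max = max(v, na.rm = TRUE))
  })
}

#' Scale CGM features for network input
#'
#' Blood glucose is multiplied by 0.01 so that its numeric range is
#' commensurate with the other channels; basal rate, bolus and carbohydrate
#' intake are min--max normalized to \[0, 1\] using statistics computed on the
#' training partition only (no test leakage). A channel that is constant on
#' the training partition maps to all zeros. Optionally (`bg_minmax = TRUE`)
#' the 0.01-scaled glucose is min--max normalized as well.
#'
#' @param x A gap-free `cgm_series`.
#' @param stats Scaling statistics from [compute_scale_stats()]; computed from
#'   `x`'s training partition when `NULL`.
#' @param bg_minmax Additionally min--max normalize the glucose channel.
#' @return The scaled series, with the statistics attached as attribute
#'   `scale_stats` (and `bg_minmax`).
#' @export
scale_features <- function(x, stats = NULL, bg_minmax = FALSE) {
  if (is.null(stats)) stats <- compute_scale_stats(x)
  if (any(stats$max < stats$min)) {
    stop("invalid scaling statistics: max < min", call. = FALSE)
  }
  rng <- function(chan) {
    row <- stats[stats$channel == chan, ]
    c(row$min, row$max)
  }
  minmax <- function(v, r) {
    if (r[2] - r[1] <= 0) rep(0, length(v)) else (v - r[1]) / (r[2] - r[1])
  }
  out <- tibble::as_tibble(x)
  out$bg <- out$bg * 0.01
  if (bg_minmax) out$bg <- minmax(out$bg, rng("bg") * 0.01)
  for (chan in c("bas", "bol", "ch")) {
    out[[chan]] <- minmax(out[[chan]], rng(chan))
  }
  out <- new_cgm_series(out, sample_minutes = attr(x, "sample_minutes") %||% 5)
  attr(out, "scale_stats") <- stats
  attr(out, "bg_minmax") <- bg_minmax
  out
}

#' Map a scaled glucose value back to mg/dL
#'
#' @param v Scaled glucose values (network output scale).
#' @param scale_stats,bg_minmax Scaling metadata as attached by
#'   [scale_features()].
#' @return Glucose in mg/dL (unclipped).
#' @export
unscale_bg <- function(v, scale_stats = NULL, bg_minmax = FALSE) {
  if (bg_minmax) {
    r <- scale_stats[scale_stats$channel == "bg", ]
    v <- v * (r$max - r$min) * 0.01 + r$min * 0.01
  }
  v * 100
}

#' Build supervised windows from a scaled series
#'
#' Each sample holds a 25-step input window (120 minutes of history plus the
#' current step, 4 features) and, per requested prediction horizon, the scaled
#' glucose value that many minutes after the window's last step. Windows are
#' built inside each train/test partition separately, so no window straddles
#' the boundary; a partition of length L yields `L - 24 - max(horizon_steps)`
#' samples (none, with a warning, when L is too short).
#'
#' @param x A gap-free, scaled `cgm_series` for a single patient (multiple
#'   patients are windowed independently and concatenated).
#' @param horizons Prediction horizons in minutes (must be multiples of the
#'   sample time).
#' @param history_steps Window length in steps (24 history steps + current).
#' @return A `windowed_dataset`: list with `inputs` (n x steps x 4 array),
#'   `targets` (named list of n-vectors, one per horizon, scaled), `meta`
#'   (tibble: patient_id, partition, time of window end), `horizon_steps`,
#'   and the scaling metadata carried over from `x`.
#' @export
make_windows <- function(x, horizons = c(30, 60, 120), history_steps = 25) {
  dt <- attr(x, "sample_minutes") %||% 5
  if (any(horizons %% dt != 0)) {
    stop("horizons must be multiples of the ", dt, "-minute sample time",
         call. = FALSE)
  }
  if (anyNA(x$bg)) stop("series has gaps; run fill_gaps() first", call. = FALSE)
  h_steps <- as.integer(horizons / dt)
  names(h_steps) <- as.character(horizons)
  max_h <- max(h_steps)

  feats <- c("bg", "bas", "bol", "ch")
  blocks <- list()
  for (pid in unique(x$patient_id)) {
    for (part in c("train", "test")) {
      p <- x[x$patient_id == pid & x$split == part, ]
      L <- nrow(p)
      if (L == 0) next
      n <- L - (history_steps - 1) - max_h
      if (n < 1) {
        warning("patient ", pid, " ", part, " partition too short for a window",
                call. = FALSE)
        next
      }
      ends <- history_steps:(history_steps + n - 1)
      X <- array(0, dim = c(n, history_steps, length(feats)))
      mat <- as.matrix(p[feats])
      for (s in seq_len(history_steps)) {
        X[, s, ] <- mat[ends - history_steps + s, ]
      }
      targets <- lapply(h_steps, function(h) p$bg[ends + h])
      blocks[[length(blocks) + 1]] <- list(
        X = X, targets = targets,
        meta = tibble::tibble(patient_id = pid, partition = part,
                              time = p$time[ends])
      )
    }
  }
  if (length(blocks) == 0) {
    return(structure(list(
      inputs = array(0, dim = c(0, history_steps, length(feats))),
      targets = stats::setNames(rep(list(numeric(0)), length(h_steps)), names(h_steps)),
      meta = tibble::tibble(patient_id = character(), partition = character(),
                            time = numeric()),
      horizon_steps = h_steps,
      scale_stats = attr(x, "scale_stats"),
      bg_minmax = attr(x, "bg_minmax") %||% FALSE
    ), class = "windowed_dataset"))
  }
  inputs <- do.call(abind_1, lapply(blocks, `[[`, "X"))
  targets <- lapply(names(h_steps), function(h) {
    unlist(lapply(blocks, function(b) b$targets[[h]]), use.names = FALSE)
  })
  names(targets) <- names(h_steps)
  structure(list(
    inputs = inputs,
    targets = targets,
    meta = dplyr::bind_rows(lapply(blocks, `[[`, "meta")),
    horizon_steps = h_steps,
    scale_stats = attr(x, "scale_stats"),
    bg_minmax = attr(x, "bg_minmax") %||% FALSE
  ), class = "windowed_dataset")
}

# bind 3D arrays along the first axis
abind_1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 0
  for (a in arrs) {
    k <- dim(a)[1]
    if (k > 0) out[at + seq_len(k), , ] <- a
    at <- at + k
  }
  out
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat("<windowed_dataset> ", dim(x$inputs)[1], " samples, ",
      dim(x$inputs)[2], " steps x ", dim(x$inputs)[3], " features; horizons: ",
      paste(names(x$horizon_steps), collapse = ", "), " min\n", sep = "")
  invisible(x)
}

#' Subset a windowed dataset by sample index
#'
#' @param ds A `windowed_dataset`.
#' @param idx Integer sample indices.
#' @return The subsetted `windowed_dataset`.
#' @export
windows_subset <- function(ds, idx) {
  structure(list(
    inputs = ds$inputs[idx, , , drop = FALSE],
    targets = lapply(ds$targets, function(t) t[idx]),
    meta = ds$meta[idx, ],
    horizon_steps = ds$horizon_steps,
    scale_stats = ds$scale_stats,
    bg_minmax = ds$bg_minmax
  ), class = "windowed_dataset")
}

#' Clip glucose predictions to the CGM hardware range
#'
#' Applied to every model output, after rescaling to mg/dL and before any
#' metric: values are bounded element-wise to \[40, 400\] mg/dL, mirroring the
#' sensor range of the data the models are trained on.
#'
#' @param values Predictions in mg/dL.
#' @param model_id Optional model name used in the error message when a
#'   non-finite prediction is encountered.
#' @return The clipped vector.
#' @export
clip_predictions <- function(values, model_id = NULL) {
  if (any(!is.finite(values))) {
    stop("non-finite prediction",
         if (!is.null(model_id)) paste0(" from model '", model_id, "'"),
         call. = FALSE)
  }
  pmin(400, pmax(40, values))
}
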