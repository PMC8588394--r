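#' Construct a CGM patient series
#'
#' A `cgm_series` is a tibble holding one or more patients' multichannel
#' continuous glucose monitoring (CGM) record on a uniform 5-minute grid.
#' Columns are `patient_id`, `time` (minutes since the start of the record),
#' `bg` (blood glucose, mg/dL; `NA` marks a sensor gap), `bas` (basal insulin
#' rate, U/h), `bol` (insulin bolus, U, zero when no bolus was given), `ch`
#' (carbohydrate intake, g, zero when no meal was logged) and `split`
#' (`"train"` or `"test"`; all test rows follow all train rows).
#'
#' @param patient_id Character scalar.
#' @param bg,bas,bol,ch Numeric vectors of equal length.
#' @param split Character vector (`"train"`/`"test"`) or `NULL`, in which case
#'   every step is labelled `"train"`.
#' @param start_min First timestamp in minutes.
#' @param sample_minutes Grid spacing in minutes (5 for the CGM sensors
#'   emulated here).
#'
#' @return A tibble of class `cgm_series`.
#' @export
cgm_series <- function(patient_id, bg, bas = NULL, bol = NULL, ch = NULL,
                       split = NULL, start_min = 0, sample_minutes = 5) {
  n <- length(bg)
  zeros <- rep(0, n)
  out <- tibble::tibble(
    patient_id = as.character(patient_id),
    time = start_min + sample_minutes * (seq_len(n) - 1),
    bg = as.numeric(bg),
    bas = if (is.null(bas)) zeros else as.numeric(bas),
    bol = if (is.null(bol)) zeros else as.numeric(bol),
    ch = if (is.null(ch)) zeros else as.numeric(ch),
    split = if (is.null(split)) rep("train", n) else as.character(split)
  )
  out <- new_cgm_series(out, sample_minutes = sample_minutes)
  validate_cgm_series(out)
  out
}

new_cgm_series <- function(x, sample_minutes = 5) {
  class(x) <- unique(c("cgm_series", class(x)))
  attr(x, "sample_minutes") <- sample_minutes
  x
}

#' Coerce a data frame to a CGM series
#'
#' @param x A data frame with columns `patient_id`, `time`, `bg`, `bas`,
#'   `bol`, `ch`, `split`.
#' @param sample_minutes Grid spacing in minutes.
#' @return A validated `cgm_series` tibble.
#' @export
as_cgm_series <- function(x, sample_minutes = 5) {
  need <- c("patient_id", "time", "bg", "bas", "bol", "ch", "split")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- new_cgm_series(tibble::as_tibble(x)[need], sample_minutes = sample_minutes)
  validate_cgm_series(out)
  out
}

#' Validate the invariants of a CGM series
#'
#' Checks, per patient: strictly increasing timestamps on a constant grid;
#' blood glucose (where present) inside the CGM hardware range 40--400 mg/dL;
#' non-negative insulin and carbohydrate channels; and a contiguous split in
#' which every test row follows every train row.
#'
#' @param x A `cgm_series`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_cgm_series <- function(x) {
  dt <- attr(x, "sample_minutes") %||% 5
  for (pid in unique(x$patient_id)) {
    p <- x[x$patient_id == pid, ]
    steps <- diff(p$time)
    if (length(steps) > 0 && any(abs(steps - dt) > 1e-8)) {
      stop("patient ", pid, ": timestamps must increase in constant ",
           dt, "-minute steps", call. = FALSE)
    }
    bg <- p$bg[!is.na(p$bg)]
    if (any(bg < 40 - 1e-9 | bg > 400 + 1e-9)) {
      stop("patient ", pid, ": bg outside the CGM range [40, 400] mg/dL",
           call. = FALSE)
    }
    for (chan in c("bas", "bol", "ch")) {
      v <- p[[chan]]
      if (anyNA(v) || any(v < 0)) {
        stop("patient ", pid, ": channel '", chan,
             "' must be non-negative with absent events encoded as 0",
             call. = FALSE)
      }
    }
    if (!all(p$split %in% c("train", "test"))) {
      stop("patient ", pid, ": split labels must be 'train' or 'test'",
           call. = FALSE)
    }
    is_test <- p$split == "test"
    if (any(is_test) && any(diff(is_test) < 0)) {
      stop("patient ", pid, ": the test partition must be a suffix of the series",
           call. = FALSE)
    }
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a CGM cohort to delimited text
#'
#' Serializes the series in a long dialect (`patient_id`, `timestamp`,
#' `channel`, `value`; missing glucose samples are dropped rather than written
#' as `NA`) alongside a JSON sidecar recording, per patient, the first test
#' timestamp.
#'
#' @param x A `cgm_series`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_cgm_csv <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  long <- tidyr::pivot_longer(
    tibble::as_tibble(x)[c("patient_id", "time", "bg", "bas", "bol", "ch")],
    cols = c("bg", "bas", "bol", "ch"),
    names_to = "channel", values_to = "value"
  )
  long <- dplyr::rename(dplyr::filter(long, !is.na(.data$value)), timestamp = "time")
  readr::write_csv(long, file.path(dir, "cgm.csv"))
  split_info <- lapply(split(x, x$patient_id), function(p) {
    ts <- p$time[p$split == "test"]
    list(test_from = if (length(ts) > 0) min(ts) else NULL)
  })
  jsonlite::write_json(split_info, file.path(dir, "split.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Read a CGM cohort from delimited text
#'
#' Inverse of [write_cgm_csv()]: reconstructs the uniform 5-minute grid per
#' patient (reintroducing `NA` for missing glucose samples) and the
#' train/test split from the JSON sidecar.
#'
#' @param dir Directory containing `cgm.csv` and `split.json`.
#' @param sample_minutes Grid spacing in minutes.
#' @return A `cgm_series` tibble.
#' @export
read_cgm_csv <- function(dir, sample_minutes = 5) {
  long <- readr::read_csv(file.path(dir, "cgm.csv"), show_col_types = FALSE)
  split_info <- jsonlite::read_json(file.path(dir, "split.json"))
  per_patient <- lapply(split(long, long$patient_id), function(p) {
    grid <- seq(min(p$timestamp), max(p$timestamp), by = sample_minutes)
    wide <- tidyr::pivot_wider(p, names_from = "channel", values_from = "value")
    idx <- match(grid, wide$timestamp)
    pid <- p$patient_id[[1]]
    test_from <- split_info[[pid]]$test_from
    tibble::tibble(
      patient_id = pid,
      time = grid,
      bg = wide$bg[idx],
      bas = ifelse(is.na(wide$bas[idx]), 0, wide$bas[idx]),
      bol = ifelse(is.na(wide$bol[idx]), 0, wide$bol[idx]),
      ch = ifelse(is.na(wide$ch[idx]), 0, wide$ch[idx]),
      split = if (is.null(test_from)) "train" else
        ifelse(grid >= test_from, "test", "train")
    )
  })
  as_cgm_series(dplyr::bind_rows(per_patient), sample_minutes = sample_minutes)
}
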