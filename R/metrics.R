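#' The seven-metric forecasting evaluation suite
#'
#' Computes, from aligned (actual, predicted) glucose pairs in mg/dL:
#' mean squared error (MSE), its root (RMSE), mean absolute error (MAE),
#' R-squared (1 - SSres/SStot around the actual mean), Pearson correlation
#' (CC), Fit (1 - sum |predicted - actual| / sum |actual - mean(actual)|,
#' the mean-predictor-normalized absolute residual; zero for the constant
#' mean predictor and negative for anything worse), and the mean absolute
#' relative difference (MARD, mean of |predicted - actual| / actual).
#'
#' With fewer than two points or zero variance in the actual values the
#' variance-normalized metrics (R2, CC, Fit) are undefined and returned as
#' `NA` with a warning; the error magnitudes are still computed.
#'
#' @param data A data frame of aligned pairs.
#' @param truth,estimate Column names of the actual and predicted values.
#' @return A one-row tibble with columns `n`, `mse`, `rmse`, `mae`, `r2`,
#'   `cc`, `fit`, `mard`.
#' @export
compute_metrics <- function(data, truth = "actual", estimate = "predicted") {
  a <- data[[truth]]
  p <- data[[estimate]]
  stopifnot(length(a) == length(p))
  if (any(a <= 0)) stop("actual values must be positive (MARD)", call. = FALSE)
  n <- length(a)
  res <- p - a
  mse <- mean(res^2)
  out <- tibble::tibble(
    n = n, mse = mse, rmse = sqrt(mse), mae = mean(abs(res)),
    r2 = NA_real_, cc = NA_real_, fit = NA_real_, mard = mean(abs(res) / a)
  )
  sst <- sum((a - mean(a))^2)
  if (n < 2 || sst <= 0) {
    warning("R2, CC and Fit are undefined (n < 2 or zero actual variance)",
            call. = FALSE)
    return(out)
  }
  out$r2 <- 1 - sum(res^2) / sst
  # a constant prediction vector has no defined correlation; report NA
  out$cc <- suppressWarnings(stats::cor(p, a))
  out$fit <- 1 - sum(abs(res)) / sum(abs(a - mean(a)))
  out
}

#' Format an aggregated metric table as models x metrics
#'
#' Pivots the long output of [aggregate_patients()] into the conventional
#' benchmark layout: one row per model, one column per metric, cells
#' rendered `mean +/- SEM`.
#'
#' @param agg Long tibble from [aggregate_patients()].
#' @param digits Decimal places in the rendered cells.
#' @return A wide tibble of character cells.
#' @export
format_metric_table <- function(agg, digits = 2) {
  agg$cell <- ifelse(
    is.na(agg$sem),
    formatC(agg$mean, digits = digits, format = "f"),
    paste0(formatC(agg$mean, digits = digits, format = "f"), " ± ",
           formatC(agg$sem, digits = digits, format = "f"))
  )
  keys <- intersect(c("model", "horizon"), names(agg))
  wide <- tidyr::pivot_wider(agg[c(keys, "metric", "cell")],
                             names_from = "metric", values_from = "cell")
  order_cols <- intersect(c(keys, "rmse", "mse", "mae", "r2", "cc", "fit",
                            "mard"), names(wide))
  wide[order_cols]
}

#' Aggregate per-patient metric rows into mean and standard error
#'
#' Rows are first averaged within patient (over folds), then summarized over
#' patients as the arithmetic mean and the standard error of the mean
#' (sample sd / sqrt(number of patients)). With a single patient the SEM is
#' reported as `NA`.
#'
#' @param rows Metric rows (as from [cross_validate()]'s `metrics`), with a
#'   `patient_id` column plus grouping columns `model` and `horizon` when
#'   present.
#' @return A long tibble: (model, horizon,) metric, mean, sem, n_patients.
#' @export
aggregate_patients <- function(rows) {
  group_cols <- intersect(c("model", "horizon"), names(rows))
  metric_cols <- intersect(c("mse", "rmse", "mae", "r2", "cc", "fit", "mard"),
                           names(rows))
  long <- tidyr::pivot_longer(
    rows[c("patient_id", group_cols, metric_cols)],
    cols = dplyr::all_of(metric_cols),
    names_to = "metric", values_to = "value"
  )
  per_patient <- dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(
      c(group_cols, "metric", "patient_id")))),
    value = mean(.data$value), .groups = "drop"
  )
  dplyr::summarise(
    dplyr::group_by(per_patient,
                    dplyr::across(dplyr::all_of(c(group_cols, "metric")))),
    mean = mean(.data$value),
    sem = ifelse(dplyr::n() > 1,
                 stats::sd(.data$value) / sqrt(dplyr::n()), NA_real_),
    n_patients = dplyr::n(),
    .groups = "drop"
  )
}
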